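substance,initial,m12_n1,m12_n3,m12_n6,m16_n1,m16_n3,m16_n6,m20_n1,m20_n3,m20_n6
Acetaldehyde,354.39,770.22,740.07,751.41,499.76,469.83,473.64,609.08,571.53,593.79
Ethyl formate,26.21,70.78,69.4,69.82,58.28,55.21,57.02,99.36,97.12,98.44
Isobutyraldehyde,0,0.04,0.02,0.03,0.04,0.02,0.03,3.63,3.27,3.54
Ethyl acetate,2668.95,3319.56,3284.1,3302.1,2773.44,2712.24,2740.59,3243.26,3229.35,3270.77
Acetal,188.56,198.51,190.77,193.38,222.62,217.2,224.82,261.88,260.49,260.88
2-butanone,5.39,6.7,6.63,6.59,6.03,6.04,6.05,6.11,6.12,6.25
Methanol,105.83,125.87,122.66,121.28,107.98,105.67,102.81,40.57,40.49,42.24
Isovaleraldehyde,42.89,15.78,16.73,18.39,21.54,22.51,24.66,55.92,55.78,56
2-pentanone,2.97,0.02,0.02,0.03,0.02,0.02,0.03,0.02,0.02,0.03
Ethyl butyrate,14.27,19.48,19.05,19.35,16.16,16.05,15.97,16.73,16.69,16.84
Sec-butyl alcohol,55.89,64.68,63.9,64.48,54.87,54.84,54.79,58.36,58.36,58.92
N-Propanol,1052.19,1151.37,1142.55,1148.04,1015.74,1014.39,1014.12,1057.42,1054.77,1065.42
Ethyl isovalerate,2.75,6.61,7.17,6.57,6.82,6.48,6.46,8.37,8.11,8.29
Butyl acetate,1.36,3.89,4.32,3.97,2.74,2.31,2.4,2.96,3.38,2.79
"1,1-diethoxy-3-methyl-Butane",16.56,0.03,0.03,0.03,0.02,0.03,0.03,0.02,0.03,0.03
Isobutanol,118.65,135.57,134.36,135.07,117.2,117.14,117.15,128.79,128.49,129.61
Isoamyl acetate,6.28,5.49,5.31,5.59,3.99,4.07,4.05,3.88,4.05,3.9
Ethyl valerate,1.78,4.26,4.73,4.65,1.92,1.73,1.68,1.81,1.85,1.86
2-Pentanol,0.47,0,0,0.54,0.43,0.41,0.45,0.52,0.47,0.4
N-butanol,47.43,54.11,53.51,54.11,45.98,45.91,45.9,49.79,49.72,50.04
2-methyl-1-butanol,56.52,368.06,365.37,366.96,56.52,56.3,56.17,61.78,61.77,62.17
3-methyl-1-butanol,190.53,272.18,270.1,271.57,194.59,193.96,193.85,213.86,213.22,215.23
Ethyl caproate,9.76,7.84,7.82,7.57,6.03,5.11,5.05,6.47,6.42,6.5
Pentanol,1.15,4.24,3.81,3.99,3.33,3.33,3.53,3.57,3.4,3.59
Vinegar buzz,28.85,40.86,40.25,40.74,33.61,33.93,33.67,35.69,34.89,34.45
Ethyl heptanoate,0.45,5.13,3.58,2.76,3.22,0.67,0,0.65,0.63,0.84
Ethyl lactate,3113.46,2798.19,2771.37,2761.83,2178.54,2237.13,2201.58,2022.28,2067.91,2091.28
Hexanol,3.61,5.44,5.24,5.3,6.11,5.69,5.55,3.8,3.82,4.05
Butyl hexanoate,0.87,2.35,2.4,2.15,0.91,0.87,0.9,0.61,0.6,0.54
Ethyl octanoate,5.58,1.11,1.61,2.19,1.78,1.78,1.76,1.41,1.44,1.46
Acetic acid,2375.73,2883.87,2839.95,2827.89,1994.04,1997.91,1963.98,1831.8,1878.21,1898.92
Furfural,246.25,201.48,199.04,198.57,159.76,163.2,160.93,153.34,157.42,159.22
Ethyl nonanoate,1.63,0.02,0.02,0.03,0.02,0.02,0.03,1.23,1.21,1.23
Propionic acid,0,12.24,11.78,11.36,16.96,15.96,15.05,81.03,84.3,85.45
Isobutyric acid,17.57,20.31,20.61,20.5,13.76,13.83,13.51,3.37,8.12,8.05
"2,3-butanediol",81.43,73.57,73.79,74.42,88.12,89.78,90.14,83.45,71.52,71.28
Ethyl decanoate,1.14,1.77,1.54,1.41,0.96,1.17,1.32,1.04,0.8,1.26
Butyrate,7.1,17.78,13.25,12.4,19.78,10.64,9.14,8.81,6.09,6.1
Isovaleric acid,21.63,27.44,26.85,26.83,19.77,19.95,19.84,14.53,14.84,15.05
Valeric acid,0.19,2.1,1.56,1.68,3.8,1.51,0.96,0.96,0.42,0.47
Ethyl phenylacetate,5.89,5.73,6.04,5.91,5.01,5.01,4.94,4.58,4.44,4.57
Hexanoic acid,7.69,18,7.55,4.58,64.64,14.21,8.03,6.66,2.92,3.45
beta-phenylethanol,12.59,17.04,16.81,16.86,12.52,12.97,12.82,14.61,14.77,14.96
Heptanoic acid,0.03,0.03,0.02,0.02,1.19,0.15,0.19,0.03,0.03,0.02
Octanoic acid,0,1.17,0,0,2.38,1.68,1.4,1.32,0.9,0.91
Ethyl palmitate,43.93,76.07,76.26,76.11,40.62,42.91,41.65,29.55,30.02,30.54
Ethyl oleate,16.42,26.82,26.4,25,16.51,17.16,16.89,10.07,10.26,10.59
Ethyl linoleate,30.83,44.57,50.22,47.68,29.44,31.45,30.6,22.03,22.62,23.27
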