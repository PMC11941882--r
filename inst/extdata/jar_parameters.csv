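jar_id,cu,fe,zn,p_max,p_min
1,0,5.12,0.0077,76.78,5.86
2,0.024,5.28,0.06,84.83,6.42
3,0.088,5.29,0.06,105.16,2.27
4,0.18,5.32,0.15,89.29,2.33
5,0.22,5.19,0.35,74.93,2.42
6,0.11,6.01,0.23,150.48,5.88
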