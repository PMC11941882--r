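jar_id,replicate,month,ion,mg_per_l
1,1,0,Ca,0.656
1,1,0,Na,0.198
1,1,0,Mg,0.094
1,1,0,Al,0.192
1,1,0,K,0.0693
1,1,0,Fe,0.135
1,1,0,Mn,0.0182
1,1,0,Cu,0.00285
1,1,0,Zn,0.0171
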