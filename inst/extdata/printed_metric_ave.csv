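case,hsc,dsc
S1C1,0,0.84
S1C2,0.11,0.842
S1C3,0.294,0.844
S1C4,0.506,0.848
S1C5,0.702,0.848
S2C1,0.462,0.637
S2C2,0.461,0.725
S2C3,0.463,0.761
S2C4,0.462,0.8
S2C5,0.462,0.844
S2C6,0.461,0.892
S2C7,0.461,0.947
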