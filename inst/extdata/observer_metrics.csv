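observer,case,hsc,dsc
Obs1,S1C1,0,0.839
Obs2,S1C1,0,0.839
Obs3,S1C1,0,0.834
Obs4,S1C1,0,0.847
Obs1,S1C2,0.11,0.843
Obs2,S1C2,0.11,0.844
Obs3,S1C2,0.109,0.834
Obs4,S1C2,0.111,0.847
Obs1,S1C3,0.293,0.844
Obs2,S1C3,0.294,0.844
Obs3,S1C3,0.292,0.838
Obs4,S1C3,0.297,0.849
Obs1,S1C4,0.503,0.847
Obs2,S1C4,0.507,0.848
Obs3,S1C4,0.506,0.845
Obs4,S1C4,0.51,0.851
Obs1,S1C5,0.7,0.848
Obs2,S1C5,0.702,0.848
Obs3,S1C5,0.701,0.845
Obs4,S1C5,0.705,0.849
Obs1,S2C1,0.46,0.638
Obs2,S2C1,0.462,0.635
Obs3,S2C1,0.461,0.634
Obs4,S2C1,0.466,0.64
Obs1,S2C2,0.461,0.723
Obs2,S2C2,0.461,0.726
Obs3,S2C2,0.459,0.72
Obs4,S2C2,0.465,0.73
Obs1,S2C3,0.462,0.759
Obs2,S2C3,0.464,0.765
Obs3,S2C3,0.459,0.755
Obs4,S2C3,0.467,0.766
Obs1,S2C4,0.46,0.797
Obs2,S2C4,0.463,0.802
Obs3,S2C4,0.461,0.797
Obs4,S2C4,0.464,0.804
Obs1,S2C5,0.461,0.841
Obs2,S2C5,0.464,0.847
Obs3,S2C5,0.459,0.838
Obs4,S2C5,0.465,0.848
Obs1,S2C6,0.458,0.888
Obs2,S2C6,0.464,0.897
Obs3,S2C6,0.46,0.887
Obs4,S2C6,0.464,0.896
Obs1,S2C7,0.458,0.945
Obs2,S2C7,0.46,0.947
Obs3,S2C7,0.461,0.944
Obs4,S2C7,0.465,0.952
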