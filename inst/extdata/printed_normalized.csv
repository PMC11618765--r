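observer,case,normalized
Obs1,S1C1,0.963
Obs2,S1C1,0.917
Obs3,S1C1,1.017
Obs4,S1C1,0.985
Obs1,S1C2,0.823
Obs2,S1C2,0.698
Obs3,S1C2,0.937
Obs4,S1C2,0.943
Obs1,S1C3,0.708
Obs2,S1C3,0.54
Obs3,S1C3,0.737
Obs4,S1C3,0.627
Obs1,S1C4,0.479
Obs2,S1C4,0.429
Obs3,S1C4,0.578
Obs4,S1C4,0.485
Obs1,S1C5,0.351
Obs2,S1C5,0.283
Obs3,S1C5,0.369
Obs4,S1C5,0.342
Obs1,S2C1,0.505
Obs2,S2C1,0.371
Obs3,S2C1,0.645
Obs4,S2C1,0.514
Obs1,S2C2,0.488
Obs2,S2C2,0.431
Obs3,S2C2,0.642
Obs4,S2C2,0.507
Obs1,S2C3,0.514
Obs2,S2C3,0.471
Obs3,S2C3,0.643
Obs4,S2C3,0.491
Obs1,S2C4,0.501
Obs2,S2C4,0.429
Obs3,S2C4,0.632
Obs4,S2C4,0.521
Obs1,S2C5,0.518
Obs2,S2C5,0.469
Obs3,S2C5,0.632
Obs4,S2C5,0.498
Obs1,S2C6,0.508
Obs2,S2C6,0.476
Obs3,S2C6,0.639
Obs4,S2C6,0.509
Obs1,S2C7,0.503
Obs2,S2C7,0.524
Obs3,S2C7,0.642
Obs4,S2C7,0.519
AVE,S1C1,0.97
AVE,S1C2,0.85
AVE,S1C3,0.653
AVE,S1C4,0.493
AVE,S1C5,0.336
AVE,S2C1,0.509
AVE,S2C2,0.517
AVE,S2C3,0.53
AVE,S2C4,0.521
AVE,S2C5,0.529
AVE,S2C6,0.533
AVE,S2C7,0.547
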