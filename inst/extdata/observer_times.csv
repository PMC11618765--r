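observer,case,seconds
Obs1,S1C1,703
Obs2,S1C1,385
Obs3,S1C1,642
Obs4,S1C1,575
Obs1,S1C2,601
Obs2,S1C2,293
Obs3,S1C2,591
Obs4,S1C2,551
Obs1,S1C3,517
Obs2,S1C3,227
Obs3,S1C3,465
Obs4,S1C3,366
Obs1,S1C4,350
Obs2,S1C4,180
Obs3,S1C4,365
Obs4,S1C4,283
Obs1,S1C5,256
Obs2,S1C5,119
Obs3,S1C5,233
Obs4,S1C5,200
Obs1,S2C1,369
Obs2,S2C1,156
Obs3,S2C1,407
Obs4,S2C1,300
Obs1,S2C2,356
Obs2,S2C2,181
Obs3,S2C2,405
Obs4,S2C2,296
Obs1,S2C3,375
Obs2,S2C3,198
Obs3,S2C3,406
Obs4,S2C3,287
Obs1,S2C4,366
Obs2,S2C4,180
Obs3,S2C4,399
Obs4,S2C4,304
Obs1,S2C5,378
Obs2,S2C5,197
Obs3,S2C5,399
Obs4,S2C5,291
Obs1,S2C6,371
Obs2,S2C6,200
Obs3,S2C6,403
Obs4,S2C6,297
Obs1,S2C7,367
Obs2,S2C7,220
Obs3,S2C7,405
Obs4,S2C7,303
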