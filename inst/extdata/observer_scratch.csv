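observer,scratch_seconds
Obs1,730
Obs2,420
Obs3,631
Obs4,584
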