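gene,subclass,source
g0001,C1,simulated
g0002,C1,simulated
g0003,C1,simulated
g0004,C1,simulated
g0005,C2,simulated
g0006,C2,simulated
g0007,C2,simulated
g0008,C2,simulated
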