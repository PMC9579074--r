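variable,f1,f2,f3
x1,0.7,0,0
x2,0.7,-0.25,0
x3,0.5,0,0.25
x4,0.45,0,0
x5,0.4,0,0
x6,0,0.8,0
x7,0.25,0.65,0
x8,0,0.55,0
x9,0,0.5,-0.25
x10,0,0.4,0
x11,0,0,0.7
x12,0,0,0.6
x13,-0.25,0,0.55
x14,0,0.25,0.5
x15,0,0,0.45
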