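factor,f1,f2,f3
f1,1,0.3,0.2
f2,0.3,1,0.3
f3,0.2,0.3,1
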