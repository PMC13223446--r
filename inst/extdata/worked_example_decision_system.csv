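id,a,b,decision
u1,0.7,0.7,1
u2,0.7,0.3,0
u3,0.7,0.3,1
u4,0.3,0.3,0
u5,0.2,0.2,0
u6,0.5,0.5,1
u7,0.4,0.4,0
u8,0.5,0.5,1
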