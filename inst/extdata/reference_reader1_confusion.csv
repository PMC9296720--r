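resident,a,b,c,d
a,15,0,0,0
b,0,16,1,0
c,0,2,13,0
d,0,0,3,10
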