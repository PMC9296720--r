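resident,a,b,c,d
a,15,0,0,0
b,1,16,0,0
c,0,4,9,2
d,0,0,0,13
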