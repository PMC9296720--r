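true,a,b,c,d
a,651,98,0,1
b,127,517,104,1
c,0,103,567,80
d,0,4,112,634
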