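feature,max_p_adjusted
variance,0.0005
skewness,0.0005
kurtosis,0.0005
entropy,0.0005
contrast,0.0005
correlation,0.002
energy,0.0005
homogeneity,0.01
SRE,1.0
LRE,0.1
GLN,0.0005
RLN,0.0005
RP,0.9
LGRE,0.4
HGRE,1.0
SRLGE,0.006
SRHGE,1.0
LRLGE,0.6
LRHGE,0.4
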