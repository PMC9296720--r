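feature,rho,p
variance,0.43,0.0005
skewness,-0.81,0.0005
kurtosis,-0.35,0.0005
entropy,-0.49,0.0005
contrast,0.48,0.0005
correlation,0.49,0.0005
energy,0.47,0.0005
homogeneity,-0.31,0.003
GLN,-0.59,0.0005
RLN,-0.66,0.0005
SRLGE,0.41,0.363
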