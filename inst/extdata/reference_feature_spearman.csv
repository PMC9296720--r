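feature_a,feature_b,rho,basis
GLN,RLN,0.8,stated
GLN,skewness,0.51,stated
RLN,variance,-0.6,encoded_moderate
RLN,kurtosis,-0.6,encoded_moderate
RLN,entropy,-0.6,encoded_moderate
skewness,SRLGE,-0.7,encoded_high
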