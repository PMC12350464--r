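patient,sequence,method,psa,psd
B,2,pipeline,58.51,62.94
B,3,pipeline,62.16,55.70
D,6,pipeline,61.90,57.89
D,7,pipeline,62.35,59.09
E,9,pipeline,64.58,58.95
E,10,pipeline,65.85,65.71
B,2,expert,NA,55
B,3,expert,NA,60
D,6,expert,NA,60
D,7,expert,NA,70
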