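task,accuracy,sensitivity,precision,specificity,f_score
3,0.75,0.65,0.47,0.79,0.52
6,0.84,0.85,0.43,0.83,0.53
7,0.71,0.72,0.83,0.75,0.76
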