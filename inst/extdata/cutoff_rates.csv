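cutoff,sensitivity,specificity
0,1.00,0.00
1,1.00,0.07
2,1.00,0.31
3,0.91,0.72
4,0.82,0.93
5,0.45,1.00
6,0.09,1.00
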