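,0,1,2,3
0,9,85,,
1,18,656,282,6
2,,4776,4139,114
3,,145,4471,3312
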