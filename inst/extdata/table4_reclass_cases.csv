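1,0,0,0
24,557,390,18
1,251,647,89
0,1,8,2
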