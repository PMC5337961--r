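2,0,0,0
80,1276,486,10
3,432,663,43
0,0,5,0
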