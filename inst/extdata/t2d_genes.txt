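CDKAL1
ADIPOQ
WFS1
NOTCH2
MAEA
THADA
PROX1
IGF2BP2
PPARG
ADAM30
GCKR
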