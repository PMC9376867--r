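A	B	96.1
B	C	97.0
C	D	80.2
A	B	94.8
E	F	95.0
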