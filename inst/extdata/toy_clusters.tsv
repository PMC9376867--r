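repX	g1_001
repX	g2_007
repY	g1_002
repY	g1_005
repZ	g2_003
repZ	g3_010
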