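source	target	sign
g6	g4	-1
g7	g4	+1
g7	g2	-1
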