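source	target	sign	strength
g1	g1	activate	1.0
g2	g2	activate	1.0
g3	g3	activate	1.0
g4	g4	activate	1.0
g1	g2	inhibit	0.5
g2	g1	inhibit	0.5
g2	g3	inhibit	0.5
g3	g2	inhibit	0.5
g3	g4	inhibit	0.5
g4	g3	inhibit	0.5
g4	g1	inhibit	0.5
g1	g4	inhibit	0.5
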