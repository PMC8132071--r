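source	target	sign	strength
HIF1s	HIF1s	activate	0.5
AMPKs	AMPKs	activate	0.5
ZEB1s	ZEB1s	activate	0.5
MIR200s	MIR200s	activate	0.5
HIF1s	AMPKs	inhibit	0.5
AMPKs	HIF1s	inhibit	0.5
ZEB1s	MIR200s	inhibit	0.5
MIR200s	ZEB1s	inhibit	0.5
HIF1s	ZEB1s	activate	0.1
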