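# Synthetic quadrastable metabolism/EMT-style switch (two coupled toggle
# switches); a synthetic construction, not a published parameterization.
nodes: [HIF1s, AMPKs, ZEB1s, MIR200s]
S: 0.5
"n": 4
k: 1
g0: 0
d: 0.02
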