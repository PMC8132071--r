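# Frozen parameters of the synthetic multistable self-activation ring
# (seven stable states at four nodes).
nodes: [g1, g2, g3, g4]
S: 0.5
"n": 4
k: 1
g0: 0
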