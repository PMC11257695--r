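targets, factors
tf, tf
g1, tf
g2, tf
g3, tf
g4, tf
g5, tf
g6, tf
g7, tf
g8, tf
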