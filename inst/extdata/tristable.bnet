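targets, factors
X, !Y & !Z
Y, !X & !Z
Z, !X & !Y
gx1, X
gx2, X
gy1, Y
gy2, Y
gz1, Z
gz2, Z
gxy, X | Y
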