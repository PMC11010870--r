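targets, factors
P, 0
Y1, P | Y2
Y2, Y1 & !(P & I1)
G1, P | G2
G2, G1 & !Y2
I1, G2
M, Y2 & !G2
R, G2
U1, P | U2
U2, U1
B1, B2 | G2
B2, B1
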