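aa,max_asa
A,129
R,274
N,195
D,193
C,167
E,223
Q,225
G,104
H,224
I,197
L,201
K,236
M,224
F,240
P,159
S,155
T,172
W,285
Y,263
V,174
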