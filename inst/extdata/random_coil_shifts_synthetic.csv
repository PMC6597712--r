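aa,CA,CB
A,52.5,19.0
C,58.3,28.6
D,54.1,40.8
E,56.7,29.7
F,57.9,39.3
G,45.0,NA
H,55.8,32.0
I,61.6,38.8
K,56.5,32.5
L,55.6,42.3
M,55.8,32.9
N,53.0,37.9
P,63.0,31.8
Q,56.2,28.8
R,56.1,30.3
S,58.1,63.2
T,62.0,69.2
V,62.6,31.8
W,57.6,29.5
Y,58.0,38.7
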