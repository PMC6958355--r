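residue	propensity
A	0.307
R	0.106
N	0.322
D	0.479
C	0.165
Q	0.336
E	0.449
G	0.265
H	0.202
I	0.279
L	0.246
K	0.111
M	0.221
F	0.195
P	0.327
S	0.281
T	0.304
W	0.172
Y	0.185
V	0.245
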