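group,emboss,bjellqvist
Nterm,8.6,7.5
Cterm,3.6,3.55
C,8.5,9
D,3.9,4.05
E,4.1,4.45
H,6.5,5.98
K,10.8,10
R,12.5,12
Y,10.1,10
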