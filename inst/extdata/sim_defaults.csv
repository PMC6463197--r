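name,rrf_true,me_true_pct,recovery_true_pct
"Hexachloro-1,3-butadiene",1.7,-5.1,95
Pentachlorobenzene,1.0,-1.9,95
Tetrachloro-m-xylene,1.0,-1.3,100
alpha-HCH,3.3,-1.2,89
Hexachlorobenzene,1.4,3.8,107
beta-HCH,2.1,9.3,88
Lindane,2.4,2.3,87
delta-HCH,2.0,3.6,91
Heptachlor,0.46,1.0,94
BDE-28,5.3,1.6,99
BDE-47,3.2,5.7,102
BDE-77,1.0,1.3,100
BDE-100,1.6,3.9,100
BDE-99,1.2,10,99
BDE-154,0.49,7.0,101
BDE-153,0.26,11,105
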