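index	genistein	hyoscyamine
e_homo	-6.24	-6.26
e_lumo	-1.82	-0.57
gap	4.42	5.69
ip	7.62	7.93
ea	0.35	-0.35
electronegativity	3.98	3.79
chemical_potential	-3.98	-3.79
hardness	7.28	8.28
softness	0.14	0.12
electrophilicity	1.09	0.86
nucleophilicity	0.92	1.16
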