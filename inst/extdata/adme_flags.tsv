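molecule	tpsa	consensus_logp	solubility_class	gi_absorption	pgp_substrate	bioavailability_score	synthetic_accessibility
genistein	90.90	2.04	Moderately soluble	high	FALSE	0.55	2.87
hyoscyamine	49.77	2.04	Soluble	high	FALSE	0.55	4.33
01	143.83	2.64	Poorly soluble	low	FALSE	0.55	6.14
02	143.83	2.64	Poorly soluble	low	FALSE	0.55	6.14
03	136.76	2.85	Poorly soluble	low	TRUE	0.55	6.55
04	129.67	2.75	Poorly soluble	low	FALSE	0.55	6.14
05	129.67	3.43	Poorly soluble	low	TRUE	0.55	6.14
06	136.76	2.63	Poorly soluble	low	TRUE	0.55	6.64
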