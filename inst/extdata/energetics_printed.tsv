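pose_id	band_gap	binding_energy
01	3.794627494	-0.621725694
02	4.068918245	-0.616909279
03	4.101571906	-0.420143761
04	3.584011382	-0.661427102998
05	3.850955059	-0.74768719
06	4.059938488	-0.313774460999
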