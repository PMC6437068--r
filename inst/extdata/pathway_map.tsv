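substrate	product	genes	kind
16:0	16:1	SCD	desaturation
18:0	18:1	SCD	desaturation
16:0	18:0	PTPLB;PECR	elongation
18:0	20:0	ELOVL3;PTPLB;PECR	elongation
20:0	22:0	ELOVL3;PTPLB;PECR	elongation
22:5n3	22:6n3	ELOVL2	elongation+beta-oxidation
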