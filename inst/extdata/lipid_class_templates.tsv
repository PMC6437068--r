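class	backbone	core_formula	n_acyls	ether_slots	sphingoid	sphingoid_hydroxyls	quant_adduct	quant_polarity
LPC	glycerophospholipid	C8H20NO6P	1	0	FALSE	NA	[M+H]+	+
PC	glycerophospholipid	C8H20NO6P	2	0	FALSE	NA	[M+H]+	+
PC O-	glycerophospholipid	C8H20NO6P	2	1	FALSE	NA	[M+H]+	+
PE	glycerophospholipid	C5H14NO6P	2	0	FALSE	NA	[M-H]-	-
PE O-	glycerophospholipid	C5H14NO6P	2	1	FALSE	NA	[M-H]-	-
TG	glycerolipid	C3H8O3	3	0	FALSE	NA	[M+NH4]+	+
SM	sphingolipid	C5H12NO3P	2	0	TRUE	2	[M+H]+	+
Cer	sphingolipid	C0	2	0	TRUE	2	[M-H]-	-
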