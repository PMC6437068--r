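class	polarity	kind	mz	label	role	min_required
LPC	+	fragment	184.073321	phosphocholine head group C5H15NO4P+	required	1
LPC	+	fragment	104.106990	choline C5H14NO+	required	1
PC	+	fragment	184.073321	phosphocholine head group C5H15NO4P+	required	2
PC	+	neutral_loss	183.066045	phosphocholine neutral loss	required	2
PC	+	acyl_fa_neutral_loss	NA	loss of fatty acyl chain as free acid	required	2
PC O-	+	fragment	184.073321	phosphocholine head group C5H15NO4P+	required	1
SM	+	fragment	184.073321	phosphocholine head group C5H15NO4P+	required	1
SM	+	fragment	264.268576	sphingoid d18:1 dehydrated fragment	optional	1
TG	+	acyl_neutral_loss	NA	loss of NH3 + fatty acyl chain	required	1
PE	-	fragment	140.011817	phosphoethanolamine anion C2H7NO4P-	required	2
PE	-	acyl_fragment	NA	fatty acyl carboxylate RCOO-	required	2
PE	-	forbidden_fragment	184.073321	phosphocholine contamination	forbidden	2
PE O-	-	fragment	140.011817	phosphoethanolamine anion C2H7NO4P-	required	2
PE O-	-	acyl_fragment	NA	fatty acyl carboxylate RCOO-	required	2
Cer	-	neutral_loss	18.010565	water loss	required	1
Cer	-	fragment	263.237506	sphingoid d18:1 base fragment	required	1
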