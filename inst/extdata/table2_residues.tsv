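position	groove_location	peptide_contacts	observed_residues	reference_residue
9	Floor	P2	YTSFH	F
114	Sidewall	P5,P6,P7	QHPEDTRSN	H
116	Floor	P9	YHTFSDNV	Y
152	Mouth	P7	EVRWMA	V
156	Mouth	P3	WLQSRAG	L
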