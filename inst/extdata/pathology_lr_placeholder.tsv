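gene	level	pattern	age_band	lr
BRCA1	receptors_grade	ER-:G3	<50	3.73
BRCA1	receptors_grade	ER-:G3	>=50	3.16
BRCA1	receptors_grade	ER-:G2	any	1.67
BRCA1	receptors_grade	ER-:G1	any	0.90
BRCA1	receptors_grade	ER+:G3	any	0.73
BRCA1	receptors_grade	ER+:G2	any	0.40
BRCA1	receptors_grade	ER+:G1	any	0.25
BRCA1	receptors	ER-	<50	2.41
BRCA1	receptors	ER-	>=50	2.01
BRCA1	receptors	ER+	any	0.51
BRCA1	grade	G3	any	1.69
BRCA1	grade	G2	any	0.81
BRCA1	grade	G1	any	0.54
BRCA2	receptors_grade	ER-:G3	any	1.20
BRCA2	receptors_grade	ER-:G2	any	1.06
BRCA2	receptors_grade	ER-:G1	any	0.95
BRCA2	receptors_grade	ER+:G3	any	1.19
BRCA2	receptors_grade	ER+:G2	any	1.08
BRCA2	receptors_grade	ER+:G1	any	0.88
BRCA2	receptors	ER-	any	1.17
BRCA2	receptors	ER+	any	1.06
BRCA2	grade	G3	any	1.20
BRCA2	grade	G2	any	0.95
BRCA2	grade	G1	any	0.79
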