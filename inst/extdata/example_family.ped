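family_id	member_id	father_id	mother_id	sex	genotype	proband	phenotype	age_dx	age_last	surgery_type	surgery_age	test_age
FAM_A	GF	.	.	1	0	0	0	.	82	.	.	.
FAM_A	GM	.	.	2	0	0	1	61	.	.	.	.
FAM_A	F	GF	GM	1	0	0	0	.	58	.	.	.
FAM_A	M	.	.	2	1	0	0	.	55	.	.	.
FAM_A	P	F	M	2	2	1	1	38	.	.	.	.
FAM_A	S1	F	M	2	2	0	1	44	.	.	.	.
FAM_A	S2	F	M	2	1	0	0	.	49	oophorectomy	42	.
FAM_B	M0	.	.	2	0	0	2	52	.	.	.	.
FAM_B	F0	.	.	1	0	0	0	.	60	.	.	.
FAM_B	P	F0	M0	2	2	1	1	41	.	.	.	.
FAM_B	S	F0	M0	2	1	0	1	45	.	.	.	.
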