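evidence_type	category	benign_count	pathogenic_count
splicing_allele_specific	None	11	0
splicing_allele_specific	Partial	2	6
splicing_allele_specific	Complete	1	5
splicing_all	None	46	0
splicing_all	Any impact	4	49
functional	None	56	0
functional	None/partial	3	0
functional	Partial	1	0
functional	Partial/complete	0	1
functional	Complete	1	15
frequency	Single observation	59	8
frequency	>= 0.0001 & < 0.01	110	0
frequency	> 0 & < 0.0001	119	3
frequency	Not observed	155	78
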