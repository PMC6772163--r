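field	cancer_type	bracket	value
hazard	breast_female	<30	0.00005
hazard	breast_female	30-39	0.0005
hazard	breast_female	40-49	0.0015
hazard	breast_female	50-59	0.002
hazard	breast_female	60-69	0.0025
hazard	breast_female	70-79	0.003
hazard	breast_female	80+	0.003
hazard	ovarian	<30	0.000005
hazard	ovarian	30-39	0.00002
hazard	ovarian	40-49	0.00005
hazard	ovarian	50-59	0.0001
hazard	ovarian	60-69	0.00015
hazard	ovarian	70-79	0.0002
hazard	ovarian	80+	0.0002
hazard	breast_male	<30	0
hazard	breast_male	30-39	0
hazard	breast_male	40-49	0
hazard	breast_male	50-59	0
hazard	breast_male	60-69	0
hazard	breast_male	70-79	0
hazard	breast_male	80+	0
hazard_ratio	breast_female	<30	20
hazard_ratio	breast_female	30-39	20
hazard_ratio	breast_female	40-49	15
hazard_ratio	breast_female	50-59	10
hazard_ratio	breast_female	60-69	8
hazard_ratio	breast_female	70-79	5
hazard_ratio	breast_female	80+	3
hazard_ratio	ovarian	<30	5
hazard_ratio	ovarian	30-39	20
hazard_ratio	ovarian	40-49	30
hazard_ratio	ovarian	50-59	30
hazard_ratio	ovarian	60-69	20
hazard_ratio	ovarian	70-79	10
hazard_ratio	ovarian	80+	5
hazard_ratio	breast_male	<30	1
hazard_ratio	breast_male	30-39	1
hazard_ratio	breast_male	40-49	1
hazard_ratio	breast_male	50-59	1
hazard_ratio	breast_male	60-69	1
hazard_ratio	breast_male	70-79	1
hazard_ratio	breast_male	80+	1
allele_frequency			0.0005
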