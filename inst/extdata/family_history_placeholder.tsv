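category	lr
strong_bc_oc_history	8.13
multiple_bc_lt50	2.64
single_bc_lt50	1.48
single_bc_ge50	0.92
ovarian_only	1.87
no_family_history	0.19
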