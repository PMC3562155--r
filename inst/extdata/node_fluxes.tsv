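condition	reaction	nominal	min	max
CAA	oaa_to_pyr	6.32	6.18	6.35
CAA	pyr_to_accoa	1.83	1.68	1.85
CAA	pyr_to_pep	4	3.96	4.01
CAA	pep_to_2pg	3.73	3.68	3.78
CAA_fructose	oaa_to_pyr	4.69	4.59	4.71
CAA_fructose	pyr_to_accoa	1.47	1.36	1.49
CAA_fructose	pyr_to_pep	2.93	2.9	2.97
CAA_fructose	pep_to_2pg	2.64	2.61	2.68
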