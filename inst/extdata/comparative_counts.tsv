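taxon	n_species	n_p450s	n_families	n_subfamilies	dominant_family	n_clusters	n_types	n_in_bgc
Cyanobacteria	114	341	36	79	CYP110	770	73	27
Bacillus	128	507	13	28	CYP107	1098	33	112
Mycobacteria	60	1784	77	132	CYP125	898	18	204
Streptomyces	48	1625	144	377	CYP107	1461	159	554
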