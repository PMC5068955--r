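table	snp	locus	chr	maf	imputation_r2	minor_allele
table3	rs115960372	LPCAT1	5	0.10	0.86	T
table4	rs35179438	TMEM252	9	0.25	0.79	A
table5	rs192804963	PARK2	6	0.21	0.66	A
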