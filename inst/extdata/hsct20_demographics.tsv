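category	item	value
subject	age_median_range	59 (27-77)
subject	sex_male	13
subject	sex_female	7
diagnosis	primary_AML	6
diagnosis	secondary_AML	6
diagnosis	MDS	7
diagnosis	CML_blast_crisis	1
donor	age_median_range	25 (16-56)
donor	HLA_matched_sibling	2
donor	haploidentical	3
donor	URD_matched	12
donor	URD_mismatched	3
graft	PBSC	20
graft	BM	0
conditioning	MA	6
conditioning	RIC	10
conditioning	non_MA	4
consolidation	yes	9
consolidation	no	11
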