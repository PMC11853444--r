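subject_id	day	compartment	field	summary_table	gene_table	note
002	84	plasma	n_mutations	3	2	summary cell lists one more mutation than the per-gene table
007	84	BM	gm_vaf	4.29	3.11	equal counts (10) but GM from per-gene VAFs disagrees as printed
012	pre	BM	n_mutations	4	5	per-gene table lists 5 gene symbols over an ambiguous 4-5 value digit string
012	pre	plasma	n_mutations	11	10	one mutation present only in the appendix-level list
013	pre	BM	n_mutations	1	0	summary reports 1/48.78 but per-gene table prints Neg
013	pre	plasma	n_mutations	5	4	one mutation present only in the appendix-level list
013	84	BM	n_mutations	2	1	summary reports 2/4.23; per-gene table lists NF2 only
013	84	plasma	n_mutations	2	1	summary reports 2/1.60; per-gene table lists TP53 only
015	84	plasma	n_mutations	1	0	summary reports 1/31.2 but per-gene table prints Neg
016	pre	plasma	gm_vaf	1.46	1.35	equal counts (5) but GM from per-gene VAFs disagrees as printed
018	pre	BM	n_mutations	6	5	one mutation present only in the appendix-level list
018	pre	plasma	n_mutations	8	7	one mutation present only in the appendix-level list
020	84	plasma	n_mutations	0	1	summary prints 0/NE; per-gene table lists DNMT3A 0.36
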