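gene	chromosome	isoform	mrna_accession	exon_skipping	novel_exons	protein_accession	amino_acid	sirtuin_domain_from_to	domain_length	pct_domain_total	nls_status	mts_status	localization
SIRT1	10	V1	NM_012238			NP_036370	747	244-498	254	34.0	present	n/a	nucleus
SIRT1	10	V2	NM_001142498	ex1, ex3	ex1'	NP_001135970	452	1-203	202	44.7	lost	n/a	cytoplasm
SIRT1	10	V3	NM_001314049	ex1, ex2, ex3	ex4'	NP_001300978	444	1-195	194	43.7	lost	n/a	cytoplasm
SIRT2	19	V1	NM_012237			NP_036369	389	65-340	275	70.7	n/a	n/a	cytoplasm
SIRT2	19	V2	NM_030593	ex2		NP_085096	352	28-303	275	78.1	n/a	n/a	cytoplasm
SIRT2	19	V3	NM_001193286	ex2, ex13, ex14		NP_001180215	234	28-234	206	88.0	n/a	n/a	cytoplasm
SIRT3	11	V1	NM_012239			NP_036371	399	126-382	256	64.2	n/a	present	mitochondria
SIRT3	11	V2	NM_001017524	ex2		NP_001017524	257	1-240	239	93.0	n/a	lost	cytoplasm
SIRT4	12	V1	NM_012240			NP_036372	314	45-314	269	85.7	n/a	present	mitochondria
SIRT5	6	V1	NM_012241			NP_036373	310	41-309	268	86.5	n/a	present	mitochondria
SIRT5	6	V2	NM_031244	ex1, ex10		NP_112534	299	41-299	258	86.3	n/a	present	mitochondria
SIRT5	6	V3	NM_001193267	ex1, ex7		NP_001180196	292	41-291	250	85.6	n/a	present	mitochondria
SIRT5	6	V4	NM_001242827	ex1, ex4		NP_001229756	202	1-202	201	99.5	n/a	lost	cytoplasm
SIRT6	19	V1	NM_016539			NP_057623	355	35-274	239	67.3	present	n/a	nucleus
SIRT6	19	V2	NM_001193285	ex6		NP_001180214	328	35-247	212	64.6	present	n/a	nucleus
SIRT6	19	V3	NM_001321058	ex2		NP_001307987	283	1-202	201	71.0	present	n/a	nucleus
SIRT6	19	V4	NM_001321059	ex3		NP_001307988	294	1-213	212	72.1	present	n/a	nucleus
SIRT6	19	V5	NM_001321060	ex7		NP_001307989	248	35-248	213	85.9	lost	n/a	cytoplasm
SIRT6	19	V6	NM_001321061	ex2, ex6		NP_001307990	256	1-175	174	68.0	present	n/a	nucleus
SIRT6	19	V7	NM_001321062	ex2, 3x3		NP_001307991	220	1-139	138	62.7	present	n/a	nucleus
SIRT6	19	V8	NM_001321063	ex3, ex7		NP_001307992	187	1-187	186	99.5	lost	n/a	cytoplasm
SIRT6	19	V9	NM_001321064	ex1, ex7		NP_001307993	176	1-176	175	99.4	lost	n/a	cytoplasm
SIRT7	17	V1	NM_016538			NP_057622	400	90-331	241	60.3	present	n/a	nucleus
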