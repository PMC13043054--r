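guide_id	target_gene	crrna_sequence	pam	pct_non_frameshift	pct_frameshift	knockout_score_pct
pcdh7b_g1	pcdh7b	TACATTACCTACCCGGACAT	CGG	57	43	43
pcdh7b_g2	pcdh7b	CGGCTGCTTCTCGCCGTCTG	TGG	20	80	80
pcdh7b_g3	pcdh7b	GAGGGAGGGCACCTAGTCTG	GGG	28	72	80
pcdh10b_g1	pcdh10b	GTGCCCGAGGAAGCGGAGCA	TGG	7	93	93
pcdh10b_g2	pcdh10b	GGGAGGCTGGCCACCGTCCA	CGG	18	82	83
pcdh10b_g3	pcdh10b	TGGCGTTGGACCACAGTTCG	GGG	60	40	40
pcdh11_g1	pcdh11	TCAAGTTTAGGTCTTTGCGC	AGG	31	69	69
pcdh11_g2	pcdh11	GGGTCAAATGCGGAAGGGAC	TGG	36	64	64
pcdh11_g3	pcdh11	TCGAGTGGTCTCATAATCTA	AGG	15	85	95
pcdh17_g1	pcdh17	TCCGACCTTGGAGAGCTGAG	GGG	3	97	100
pcdh17_g2	pcdh17	CTGGCCCATGACCCAGATTT	AGG	43	57	61
pcdh17_g3	pcdh17	GCAATGGGCAGCTCCAGTGT	AGG	9	91	91
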