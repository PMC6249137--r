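snp_id	gene	effect_allele	eaf	or_overall	or_sun_sensitive	or_not_sensitive	is_mc1r	pathways
D84E	MC1R	A	0.010	2.18	1.70	3.00	TRUE	pigmentation
V60L	MC1R	T	0.120	1.74	1.40	2.20	TRUE	pigmentation
V92M	MC1R	A	0.090	1.70	1.40	2.10	TRUE	pigmentation
R151C	MC1R	T	0.080	2.59	2.00	3.40	TRUE	pigmentation
I155T	MC1R	C	0.010	2.60	2.00	3.40	TRUE	pigmentation
R160W	MC1R	T	0.070	1.47	1.30	1.90	TRUE	pigmentation
R163Q	MC1R	A	0.040	1.22	1.10	1.45	TRUE	pigmentation
D294H	MC1R	C	0.020	2.20	1.80	3.00	TRUE	pigmentation
rs62211989	ASIP	G	0.100	1.90	NA	NA	FALSE	pigmentation
rs7274597	ASIP	A	0.060	0.50	NA	NA	FALSE	pigmentation
rs1393350	TYR	A	0.260	1.32	NA	NA	FALSE	pigmentation
rs1042602	TYR	A	0.360	1.15	NA	NA	FALSE	pigmentation
rs1408799	TYRP1	C	0.300	1.15	NA	NA	FALSE	pigmentation
rs2733832	TYRP1	T	0.350	1.10	NA	NA	FALSE	pigmentation
rs16891982	SLC45A2	G	0.950	1.60	NA	NA	FALSE	pigmentation
rs35391	SLC45A2	C	0.200	1.10	NA	NA	FALSE	pigmentation
rs1800407	OCA2	A	0.070	1.15	NA	NA	FALSE	pigmentation
rs4778138	OCA2	A	0.150	1.12	NA	NA	FALSE	pigmentation
rs1800414	OCA2	T	0.020	1.08	NA	NA	FALSE	pigmentation
rs7412746	ARNT	T	0.450	0.85	NA	NA	FALSE	pigmentation
rs6949072	AGR3	T	0.350	1.28	NA	NA	FALSE	pigmentation
rs34585474	AGR3	A	0.300	1.27	NA	NA	FALSE	pigmentation
rs7781130	AGR3	G	0.100	1.59	NA	NA	FALSE	pigmentation
rs16953002	FTO	A	0.200	1.27	NA	NA	FALSE	pigmentation
rs113908778	RAD23B	T	0.040	0.55	NA	NA	FALSE	pigmentation
rs4436178	RAD23B	C	0.050	1.87	NA	NA	FALSE	pigmentation
rs700635	CASP8	C	0.300	1.27	NA	NA	FALSE	pigmentation
rs13016963	CASP8	A	0.400	1.10	NA	NA	FALSE	pigmentation
rs132985	PLA2G6	C	0.350	1.19	NA	NA	FALSE	pigmentation,nevus
rs149617956	MITF	A	0.010	2.20	NA	NA	FALSE	pigmentation,nevus
rs76699054	CCND1	T	0.050	1.40	NA	NA	FALSE	pigmentation,nevus
rs3731217	CDKN2A	G	0.140	0.79	NA	NA	FALSE	nevus,telomere_senescence_other
rs871024	CDKN2A	A	0.300	1.15	NA	NA	FALSE	nevus,telomere_senescence_other
rs45430	MX2	G	0.400	0.72	NA	NA	FALSE	nevus,telomere_senescence_other
rs6517661	MX2	A	0.250	0.75	NA	NA	FALSE	nevus,telomere_senescence_other
rs443099	MX2	T	0.300	0.90	NA	NA	FALSE	nevus,telomere_senescence_other
rs12527588	CDKAL1	T	0.050	1.56	NA	NA	FALSE	nevus
rs7776158	CDKAL1	C	0.350	1.36	NA	NA	FALSE	nevus
rs9328323	CDKAL1	A	0.300	1.10	NA	NA	FALSE	nevus
rs3219090	PARP1	T	0.350	0.73	NA	NA	FALSE	nevus
rs2695237	PARP1	C	0.300	0.90	NA	NA	FALSE	nevus
rs2736100	TERT	C	0.500	0.74	NA	NA	FALSE	telomere_senescence_other
rs401681	TERT	T	0.450	0.90	NA	NA	FALSE	telomere_senescence_other
rs2487999	OBFC1	C	0.100	1.40	NA	NA	FALSE	telomere_senescence_other
rs1801516	ATM	A	0.150	0.77	NA	NA	FALSE	telomere_senescence_other
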