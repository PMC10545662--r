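# RECONSTRUCTION fixture: per-family prior (original report) and current (re-evaluation)
# clinical conclusions for the 152-family consanguineous NDD cohort. The source study prints
# the marginal numbers (56 families previously diagnosed = 37% yield; 11 downgrade families
# -> 30%; +12 novel diagnoses +5 newly established gene-disease associations -> 41%; 28
# families with a clinically relevant change = 10 variant downgrades + 1 GDA downgrade + 5
# GDA establishments + 12 novel diagnoses) but not the full per-family composition; this
# table is ONE consistent assignment reproducing all of them, with the 28 change families
# disjoint. Named families are transcribed; F-prefixed families are generic fill.
family_id	stratum	n_affected	prior	current	change_events
MR205	multiplex_3	3	pathogenic	negative	variant_downgrade
MR326	multiplex_2	2	pathogenic	vus	variant_downgrade
MR154	multiplex_2	2	likely_pathogenic	vus	variant_downgrade
MR-SYR-04	multiplex_2	2	likely_pathogenic	vus	variant_downgrade
MR319	multiplex_2	2	likely_pathogenic	vus	variant_downgrade
MR081	multiplex_2	2	likely_pathogenic	vus	variant_downgrade
MR-ER-3171	simplex	1	likely_pathogenic	vus	variant_downgrade
MR058	simplex	1	likely_pathogenic	vus	variant_downgrade
MR-SYR-34	multiplex_3	3	likely_pathogenic	vus	variant_downgrade
MR305	simplex	1	likely_pathogenic	vus	variant_downgrade
MR092	multiplex_2	2	likely_pathogenic	candidate_gene	gda_downgrade
MR333	simplex	1	vus	pathogenic	novel_diagnosis
MR-SYR-28	multiplex_2	2	candidate_gene	pathogenic	novel_diagnosis
MR136	simplex	1	candidate_gene	likely_pathogenic	novel_diagnosis
MR-DIV-02	multiplex_2	2	candidate_gene	likely_pathogenic	novel_diagnosis
MR-DIV-01	multiplex_2	2	candidate_gene	pathogenic	novel_diagnosis
MR152	multiplex_2	2	negative	pathogenic	novel_diagnosis
MR-SYR-49b	simplex	1	negative	pathogenic	novel_diagnosis
MR128	simplex	1	negative	pathogenic	novel_diagnosis
MR-TUR-05	simplex	1	negative	pathogenic	novel_diagnosis
MR073	multiplex_3	3	negative	likely_pathogenic	novel_diagnosis
MR125	multiplex_2	2	negative	pathogenic	novel_diagnosis
MR-SYR-49c	simplex	1	negative	pathogenic	novel_diagnosis
MR124	multiplex_2	2	negative	vus	
MR145	multiplex_2	2	negative	vus	
MR-SYR-06	multiplex_4plus	5	negative	vus	
MR-SYR-14	multiplex_2	2	negative	vus	
F001	simplex	1	pathogenic	pathogenic	
F002	simplex	1	pathogenic	pathogenic	
F003	simplex	1	pathogenic	pathogenic	
F004	simplex	1	pathogenic	pathogenic	
F005	simplex	1	pathogenic	pathogenic	
F006	simplex	1	pathogenic	pathogenic	
F007	simplex	1	pathogenic	pathogenic	
F008	simplex	1	pathogenic	pathogenic	
F009	simplex	1	pathogenic	pathogenic	
F010	simplex	1	pathogenic	pathogenic	
F011	simplex	1	pathogenic	pathogenic	
F012	simplex	1	pathogenic	pathogenic	
F013	simplex	1	pathogenic	pathogenic	
F014	simplex	1	pathogenic	pathogenic	
F015	simplex	1	pathogenic	pathogenic	
F016	simplex	1	pathogenic	pathogenic	
F017	simplex	1	pathogenic	pathogenic	
F018	simplex	1	pathogenic	pathogenic	
F019	simplex	1	pathogenic	pathogenic	
F020	simplex	1	pathogenic	pathogenic	
F021	simplex	1	pathogenic	pathogenic	
F022	simplex	1	pathogenic	pathogenic	
F023	simplex	1	pathogenic	pathogenic	
F024	simplex	1	pathogenic	pathogenic	
F025	simplex	1	pathogenic	pathogenic	
F026	simplex	1	pathogenic	pathogenic	
F027	simplex	1	pathogenic	pathogenic	
F028	simplex	1	pathogenic	likely_pathogenic	
F029	simplex	1	pathogenic	likely_pathogenic	
F030	simplex	1	pathogenic	likely_pathogenic	
F031	simplex	1	pathogenic	likely_pathogenic	
F032	simplex	1	pathogenic	likely_pathogenic	
F033	simplex	1	pathogenic	likely_pathogenic	
F034	simplex	1	pathogenic	likely_pathogenic	
F035	simplex	1	likely_pathogenic	pathogenic	
F036	multiplex_2	2	likely_pathogenic	pathogenic	
F037	multiplex_2	2	likely_pathogenic	pathogenic	
F038	multiplex_2	2	likely_pathogenic	pathogenic	
F039	multiplex_2	2	likely_pathogenic	pathogenic	
F040	multiplex_2	2	likely_pathogenic	pathogenic	
F041	multiplex_2	2	likely_pathogenic	likely_pathogenic	
F042	multiplex_2	2	likely_pathogenic	likely_pathogenic	
F043	multiplex_2	2	likely_pathogenic	likely_pathogenic	
F044	multiplex_2	2	likely_pathogenic	likely_pathogenic	
F045	multiplex_2	2	likely_pathogenic	likely_pathogenic	
F046	multiplex_2	2	vus	candidate_gene	
F047	multiplex_2	2	vus	vus	
F048	multiplex_2	2	vus	vus	
F049	multiplex_2	2	vus	vus	
F050	multiplex_2	2	candidate_gene	likely_pathogenic	gda_established
F051	multiplex_2	2	candidate_gene	likely_pathogenic	gda_established
F052	multiplex_2	2	candidate_gene	likely_pathogenic	gda_established
F053	multiplex_2	2	candidate_gene	likely_pathogenic	gda_established
F054	multiplex_2	2	candidate_gene	likely_pathogenic	gda_established
F055	multiplex_2	2	candidate_gene	candidate_gene	
F056	multiplex_2	2	candidate_gene	candidate_gene	
F057	multiplex_2	2	candidate_gene	candidate_gene	
F058	multiplex_2	2	candidate_gene	candidate_gene	
F059	multiplex_2	2	candidate_gene	candidate_gene	
F060	multiplex_2	2	candidate_gene	candidate_gene	
F061	multiplex_2	2	candidate_gene	candidate_gene	
F062	multiplex_2	2	candidate_gene	candidate_gene	
F063	multiplex_2	2	candidate_gene	candidate_gene	
F064	multiplex_2	2	candidate_gene	candidate_gene	
F065	multiplex_2	2	candidate_gene	candidate_gene	
F066	multiplex_2	2	candidate_gene	candidate_gene	
F067	multiplex_2	2	candidate_gene	candidate_gene	
F068	multiplex_2	2	candidate_gene	candidate_gene	
F069	multiplex_2	2	candidate_gene	candidate_gene	
F070	multiplex_2	2	candidate_gene	candidate_gene	
F071	multiplex_2	2	candidate_gene	candidate_gene	
F072	multiplex_2	2	candidate_gene	candidate_gene	
F073	multiplex_2	2	candidate_gene	candidate_gene	
F074	multiplex_2	2	candidate_gene	candidate_gene	
F075	multiplex_2	2	candidate_gene	candidate_gene	
F076	multiplex_2	2	candidate_gene	candidate_gene	
F077	multiplex_2	2	candidate_gene	candidate_gene	
F078	multiplex_2	2	candidate_gene	candidate_gene	
F079	multiplex_2	2	candidate_gene	candidate_gene	
F080	multiplex_2	2	candidate_gene	candidate_gene	
F081	multiplex_2	2	candidate_gene	candidate_gene	
F082	multiplex_2	2	candidate_gene	candidate_gene	
F083	multiplex_2	2	candidate_gene	candidate_gene	
F084	multiplex_2	2	candidate_gene	candidate_gene	
F085	multiplex_2	2	candidate_gene	candidate_gene	
F086	multiplex_2	2	candidate_gene	candidate_gene	
F087	multiplex_2	2	candidate_gene	candidate_gene	
F088	multiplex_2	2	candidate_gene	candidate_gene	
F089	multiplex_2	2	candidate_gene	candidate_gene	
F090	multiplex_2	2	candidate_gene	candidate_gene	
F091	multiplex_2	2	candidate_gene	candidate_gene	
F092	multiplex_2	2	candidate_gene	candidate_gene	
F093	multiplex_2	2	candidate_gene	candidate_gene	
F094	multiplex_2	2	negative	negative	
F095	multiplex_2	2	negative	negative	
F096	multiplex_2	2	negative	negative	
F097	multiplex_2	2	negative	negative	
F098	multiplex_2	2	negative	negative	
F099	multiplex_2	2	negative	negative	
F100	multiplex_2	2	negative	negative	
F101	multiplex_3	3	negative	negative	
F102	multiplex_3	3	negative	negative	
F103	multiplex_3	3	negative	negative	
F104	multiplex_3	3	negative	negative	
F105	multiplex_3	3	negative	negative	
F106	multiplex_3	3	negative	negative	
F107	multiplex_3	3	negative	negative	
F108	multiplex_3	3	negative	negative	
F109	multiplex_3	3	negative	negative	
F110	multiplex_3	3	negative	negative	
F111	multiplex_3	3	negative	negative	
F112	multiplex_3	3	negative	negative	
F113	multiplex_3	3	negative	negative	
F114	multiplex_3	3	negative	negative	
F115	multiplex_3	3	negative	negative	
F116	multiplex_3	3	negative	negative	
F117	multiplex_3	3	negative	negative	
F118	multiplex_3	3	negative	negative	
F119	multiplex_3	3	negative	negative	
F120	multiplex_3	3	negative	negative	
F121	multiplex_3	3	negative	negative	
F122	multiplex_4plus	4	negative	negative	
F123	multiplex_4plus	4	negative	negative	
F124	multiplex_4plus	4	negative	negative	
F125	multiplex_4plus	4	negative	negative	
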