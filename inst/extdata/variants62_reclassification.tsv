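# RECONSTRUCTION fixture: prior and re-evaluated five-tier classifications of the 62
# variants the original report classified as (likely) pathogenic or VUS. Marginals follow
# the source study's results (37 P in 36 families: 28 stay P, 7 to LP, 1 to B, 1 to VUS;
# 20 LP: 6 to P, 5 stay LP, 8 to VUS, 1 not classified after a gene-association downgrade;
# 5 VUS: 3 stay, 1 to B, 1 not classified); generic GENE/F identifiers are fill where the
# study does not print the row. current_tier NC = not classified; gda_change notes the
# association-level reason.
variant_id	family_id	gene	prior_tier	current_tier	gda_change
V01	F001	GENE01a	P	P	none
V02	F001	GENE01b	P	P	none
V03	F002	GENE02	P	P	none
V04	F003	GENE03	P	P	none
V05	F004	GENE04	P	P	none
V06	F005	GENE05	P	P	none
V07	F006	GENE06	P	P	none
V08	F007	GENE07	P	P	none
V09	F008	GENE08	P	P	none
V10	F009	GENE09	P	P	none
V11	F010	GENE10	P	P	none
V12	F011	GENE11	P	P	none
V13	F012	GENE12	P	P	none
V14	F013	GENE13	P	P	none
V15	F014	GENE14	P	P	none
V16	F015	GENE15	P	P	none
V17	F016	GENE16	P	P	none
V18	F017	GENE17	P	P	none
V19	F018	GENE18	P	P	none
V20	F019	GENE19	P	P	none
V21	F020	GENE20	P	P	none
V22	F021	GENE21	P	P	none
V23	F022	GENE22	P	P	none
V24	F023	GENE23	P	P	none
V25	F024	GENE24	P	P	none
V26	F025	GENE25	P	P	none
V27	F026	GENE26	P	P	none
V28	F027	GENE27	P	P	none
V29	F028	GENE28	P	LP	none
V30	F029	GENE29	P	LP	none
V31	F030	GENE30	P	LP	none
V32	F031	GENE31	P	LP	none
V33	F032	GENE32	P	LP	none
V34	F033	GENE33	P	LP	none
V35	F034	GENE34	P	LP	none
V36	MR205	DARS2	P	B	none
V37	MR326	LINS1	P	VUS	none
V38	F035	GENE35	LP	P	none
V39	F036	GENE36	LP	P	none
V40	F037	GENE37	LP	P	none
V41	F038	GENE38	LP	P	none
V42	F039	GENE39	LP	P	none
V43	F040	GENE40	LP	P	none
V44	F041	GENE41	LP	LP	none
V45	F042	GENE42	LP	LP	none
V46	F043	GENE43	LP	LP	none
V47	F044	GENE44	LP	LP	none
V48	F045	GENE45	LP	LP	none
V49	MR154	FOXRED1	LP	VUS	none
V50	MR-SYR-04	HACE1	LP	VUS	none
V51	MR319	MTHFR	LP	VUS	none
V52	MR081	TRMT10A	LP	VUS	none
V53	MR-ER-3171	UBE3B	LP	VUS	none
V54	MR058	SLC6A8	LP	VUS	none
V55	MR-SYR-34	ADGRG1	LP	VUS	none
V56	MR305	PIGA	LP	VUS	none
V57	MR092	TSEN15	LP	NC	downgraded
V58	F047	GENE47	VUS	VUS	none
V59	F048	GENE48	VUS	VUS	none
V60	F049	GENE49	VUS	VUS	none
V61	MR333	TRAPPC9	VUS	B	none
V62	F046	KDM6B	VUS	NC	uncertain
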