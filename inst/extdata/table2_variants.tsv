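# Transcription of the published table of clinically relevant changes in variant classification
# after re-evaluation (11 rows: 10 variant re-classifications + 1 gene-disease-association
# downgrade, TSEN15). Evidence counts keep the printed ">"-prefixed lower bounds.
# prior_tier is taken from the accompanying results text (the DARS2 and LINS1 variants were
# previously reported pathogenic, the others likely pathogenic). n_groups transcribes the
# printed publications count; for TSEN15 no publications count is printed and a single
# reporting group is the only value consistent with its printed tier (assumption).
# current_tier "NC" = not classified (association no longer established).
family_id	n_affected	sex	gene	cdna	protein	inheritance	gene_classification	n_affected_reported	n_families	n_groups	has_functional	prior_tier	criteria	current_tier	explains_phenotype
MR205	3	m	DARS2	c.228-12C>G	p.?	AR	established	11	8	2	FALSE	P	BS1,BS2	B	no
MR154	2	m	FOXRED1	c.874G>A	p.(Gly292Arg)	AR	established	8	7	>3	TRUE	LP	PM2,PM3,PP3	VUS	no
MR-SYR-04	2	f	HACE1	c.402+5G>A	p.?	AR	established	>14	>6	>2	FALSE	LP	PM2,PM3_Supporting,PP3	VUS	no
MR319	2	f	MTHFR	c.199C>T	p.(Pro67Ser)	AR	established	>20	>20	>2	FALSE	LP	PM2,PM3_Supporting,PP3	VUS	no
MR081	2	m	TRMT10A	c.348G>C	p.(Lys116Asn)	AR	established	>6	>3	>3	FALSE	LP	PM2,PM3_Supporting	VUS	no
MR326	2	fm	LINS1	c.786_842del	p.(Arg263_Ser281del)	AR	established	>7	>3	>2	FALSE	P	PM2,PM3_Supporting,PM4	VUS	no
MR-ER-3171	1	m	UBE3B	c.[1445T>A;1616T>C]	p.[(Leu539Pro;Leu482His)]	AR	established	>9	>7	>2	FALSE	LP	PM2,PM3,PP3	VUS	no
MR058	1	m	SLC6A8	c.644A>G	p.(Glu215Gly)	XL	established	>10	>9	>3	FALSE	LP	PM2,PM3_Supporting,PP3	VUS	no
MR-SYR-34	3	fm	ADGRG1	c.64+5G>A	p.?	AR	established	>12	>12	>3	FALSE	LP	PM2,PM3_Supporting	VUS	no
MR305	1	m	PIGA	c.1261G>C	p.(Gly421Arg)	XL	established	>14	>7	>3	FALSE	LP	PM2,PM3_Supporting,PP3	VUS	no
MR092	2	m	TSEN15	c.346C>T	p.(His116Tyr)	AR	published_candidate	5	3	1	FALSE	LP		NC	NA
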