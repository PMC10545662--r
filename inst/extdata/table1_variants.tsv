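# Transcription of the published table of previously undetected variants identified in re-analysis
# (16 established-gene rows + 2 weak-candidate rows; criteria strings verbatim, including the
# "PS4_supporting" casing and the parenthetical comment in the YARS1 row).
# Screening annotations (consequence, zygosity, protein_position, popmax_af, quality_pass) are
# derived from the printed HGVS descriptions and inheritance modes; popmax_af values are synthetic
# stand-ins consistent with "absent or very rare in references".
family_id	n_affected	sex	gene	cdna	protein	inheritance	gene_classification	criteria	reported_tier	explains_phenotype	consequence	zygosity	protein_position	popmax_af	quality_pass
MR152	2	m	ADD3	c.1100G>A	p.(Gly367Asp)	AR	established	PS3,PM2,PM3,PP1_Moderate	P	yes	missense	homozygous	367	0	TRUE
MR333	1	m	ADNP	c.2496_2499del	p.(Asn832Lysfs*81)	AD	established	PVS1,PS2_Strong,PM2	P	yes	frameshift	heterozygous	NA	0	TRUE
MR-SYR-14	2	fm	ASXL3	c.4462_4465del	p.(Thr1488Serfs*17)	AD	established	PVS1_Strong,PM2,BS3	VUS	no	frameshift	heterozygous	NA	0	TRUE
MR-DIV-01	2	m	C12orf57	c.1A>G	p.0?	AR	established	PVS1_Moderate,PS4_Supporting,PM2,PM3,PP1_Strong	P	yes	start_lost	homozygous	NA	0	TRUE
MR-SYR-49b	1	f	DEGS1	c.764A>G	p.(Asn255Ser)	AR	established	PS3,PM2,PM3,PP1_Moderate	P	yes	missense	homozygous	255	0	TRUE
MR128	1	m	ESPN	c.1916-1G>C	p.0?	AR	established	PVS1,PM2,PM3_Supporting	P	partially	splice_acceptor	homozygous	NA	0	TRUE
MR-SYR-28	2	fm	GCDH	c.1204C>T	p.(Arg402Trp)	AR	established	PS3,PS4_Supporting,PM2,PM3_Strong,PP4	P	yes	missense	homozygous	402	0.0001	TRUE
MR136	1	f	GRIN2A	c.2077A>G	p.(Asn693Asp)	AD	established	PS2_Moderate,PM1,PM2,PP3	LP	yes	missense	heterozygous	693	0	TRUE
MR-TUR-05	1	f	HNRNPH2	c.616C>T	p.(Arg206Trp)	AD	established	PS2_VeryStrong,PS4_Moderate,PM2	P	yes	missense	heterozygous	206	0	TRUE
MR124	2	m	SCN2A	c.4606A>G	p.(Ser1536Gly)	AD	established	PM2,PP3	VUS	no	missense	heterozygous	1536	0	TRUE
MR-SYR-06	5	f	SLC35A1	c.508-6T>C	p.?	AR	established	PM2	VUS	no	intronic	homozygous	NA	0	TRUE
MR073	3	m	TAF1	c.2590C>T	p.(Arg864Trp)	XL	established	PM2,PP1_Moderate,PP2,PP3	LP	yes	missense	hemizygous	864	0	TRUE
MR125	2	m	YARS1	c.1099C>T	p.(Arg367Trp)	AR	established	PS4_supporting,PM2,PM3,PP1_Strong,PP3(accordingtounpublisheddata)	P	yes	missense	homozygous	367	0	TRUE
MR-SYR-49c	1	m	ZEB2	c.2177_2178del	p.(Ser726Phefs*29)	AD	established	PVS1,PM2,PP4_Moderate	P	yes	frameshift	heterozygous	NA	0	TRUE
MR145	2	m	ZMIZ1	c.418T>C	p.(Ser140Pro)	AD	established	PM2,PP3	VUS	no	missense	heterozygous	140	0	TRUE
MR-DIV-02	2	fm	ZNF292	c.3460_3463del	p.(Val1154Ilefs*7)	AD	established	PVS1_Strong,PM2	LP	partially	frameshift	heterozygous	NA	0	TRUE
MR-SYR-21	2	m	ARHGEF6	c.257A>C	p.(Asp86Ala)	XL	weak_candidate		NA	NA	missense	hemizygous	86	0	TRUE
MR071a	1	f	ZNF143	c.44_45del	p.(Glu15Valfs*25)	AR	weak_candidate		NA	NA	frameshift	homozygous	NA	0	TRUE
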