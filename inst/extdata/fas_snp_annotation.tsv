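variant_id	chromosome	position	nearest_gene	location	major_allele	minor_allele	maf_pct	hwe_p	phenotype	notes
rs115675705	6	34094919	GRM4	intron	T	C	1.4	1	HDL
rs117788606	7	72921771	BAZ1B	intron	A	G	0.7	1	TG
rs11983997	7	72939244	BAZ1B	upstream	C	G	20.0	0.2	TG
rs80189144	7	72939939	BAZ1B	upstream	T	C	13.2	0.1	TG
rs799157	7	73020301	MLXIPL	synonymous	C	T	3.9	1	LDL
rs117860853	8	19722204	LPL	upstream	G	A	1.8	1	HDL
rs142084074	8	19768150	LOC107986921	intron	G	A	0.7	1	TG
rs144018203	11	116916060	SIK3	intron	G	C	0.7	1	HDL.TG
rs112803755	13	20790451	GJB6	downstream	A	G	1.4	1	TG
rs55707100	15	43820717	MAP1A	missense	C	T	4.6	1	TG
rs148931404	16	56914455	SLC12A3	intron	C	T	1.1	1	HDL
rs147438979	17	42061277	PYY	intron	G	C	1.8	1	HDL
rs77542162	17	67081278	ABCA6	missense	T	C	0.4	1	LDL.TC
rs141844019	19	19365178	HAPLN4	downstream	G	A	1.1	1	TG
rs112952132	19	45198060	LOC107985305	intron	G	A	0.7	1	LDL
rs147166404	0	1	NA	NA	A	G	0.0	NA	NA	monomorphic; coordinates and alleles are synthetic placeholders
rs530804537	0	2	NA	NA	A	G	0.0	NA	NA	monomorphic; coordinates and alleles are synthetic placeholders
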