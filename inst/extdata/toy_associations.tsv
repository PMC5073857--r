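rsid	pmid	study_title	phenotype	phenotype_category	p_value	allele	maf	chrom	pos	region_type	gene	aa_change	polyphen2	sift	evod
rs1001	20000001	GWAS of type 1 diabetes	Type 1 diabetes	Metabolic	1e-08	A	0.30	chr6	31540141	missense	LTA	T60N	benign	tolerated	neutral
rs1002	20000001	GWAS of type 1 diabetes	Type 1 diabetes	Metabolic	1e-06	C	0.12	chr6	31543031	intron	TNF
rs1003	20000002	GWAS of myocardial infarction	Myocardial infarction	Cardiovascular	1e-04	G	0.45	chr1	1005001	intron
rs1004	20000002	GWAS of myocardial infarction	Myocardial infarction	Cardiovascular	1e-03	T	0.05	chr2	2005002	3'UTR	FTO
rs1005	20000003	GWAS of height	Height	Anthropometric	0.04	A	0.25	chr3	3005003	intergenic
rs1006	20000003	GWAS of height	Height	Anthropometric	0.2	G	0.10	chr4	4005004	intron
rs1001	20000001	GWAS of type 1 diabetes	Type 1 diabetes	Metabolic	1e-08	A	0.30	chr6	31540141	missense	LTA	T60N	benign	tolerated	neutral
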