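# Published pathogenic predicted loss-of-function channelopathy variants
# with curated ACMG/AMP attribute strings and printed classifications.
# unique = 1 marks variants reported only in the study cohort.
gene	hgvs_c	hgvs_p	dbsnp_id	lof_type	functional_evidence	clinvar_sig	attributes	klass	tier	unique
CASQ2	c.706G>T	p.E236*	NA	stopgain	NA	NA	PVS1PM2PP3	Pathogenic	Ic	0
CASQ2	c.420+2T>C	NA	NA	splicing	NA	NA	PVS1PM2PP3	Pathogenic	Ic	1
TRDN	c.1537C>T	p.Q513*	rs757355311	stopgain	NA	Pathogenic	PVS1PM2PP3PP5	Pathogenic	Id	0
PKP2	c.1237C>T	p.R413*	rs372827156	stopgain	Heterozygotes for the variant showed ARVC phenotype in a family	Pathogenic	PVS1PM2PP1PP3PP5	Pathogenic	Id	0
KCNQ1	c.360del	p.W120*	NA	frameshift_deletion	NA	NA	PVS1PM2PP3	Pathogenic	Ic	1
KCNQ1	c.524_534dup	p.G179Sfs*62	rs879255588	frameshift_insertion	NA	Pathogenic/likely_pathogenic	PVS1PP5PM2PP3	Pathogenic	Id	0
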