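# Published pathogenic / likely pathogenic nonsynonymous channelopathy
# variants with their curated ACMG/AMP attribute strings and printed
# classifications. unique = 1 marks variants reported only in the study
# cohort (absent from global population datasets, databases and literature).
gene	hgvs_c	hgvs_p	dbsnp_id	functional_evidence	clinvar_sig	attributes	klass	tier	unique
KCND3	c.1348C>T	p.L450F	rs150401343	Gain of function of KV4.3/KChIP2-encoded channels (PMID: 26016905)	Conflicting_interpretations_of_pathogenicity	PS3PM2PP2BP4	Likely_pathogenic	II	0
SCN5A	c.6046G>A	p.V2016M	rs762981322	Loss of function by reduced cell surface expression and peak Na+ current (PMID: 24895455; PMID: 26282245); gain of function by protein kinase A or C activation (PMID: 26282245)	Conflicting_interpretations_of_pathogenicity	PS3PM2PP3	Likely_pathogenic	II	0
KCNH2	c.2467C>T	p.R823W	rs199473538	Trafficking defect (PMID: 16432067); failure to return to normal repolarisation (PMID: 23303164)	Pathogenic/likely_pathogenic	PS3PM1PM2PP3PP5BP1	Pathogenic	IIIb	0
KCNE3	c.49G>A	p.V17M	rs773287275	Gain of function on Kv4.3/KCNE3 and Kv11.1/KCNE3 generated currents (PMID: 18209471)	Uncertain_significance	PS3PM2PP3	Likely_pathogenic	II	0
SCN3B	c.328G>A	p.V110I	rs147205617	Loss of function by reducing sodium current (PMID: 23257389)	Conflicting_interpretations_of_pathogenicity	PS3PM1PP3	Likely_pathogenic	II	0
CACNA1C	c.2573G>A	p.R858H	rs786205753	Gain of function on ICa (PMID: 24728418)	Pathogenic/likely_pathogenic	PS3PM2PP2PP3PP5	Likely_pathogenic	II	0
KCNE2	c.170T>C	p.I57T	rs74315448	Gain of function of Ito (PMID: 20042375); loss of function of IKs (PMID: 11101505); loss of function of IKr (PMID: 10219239)	Conflicting_interpretations_of_pathogenicity	PS3PM1PP2PP3	Likely_pathogenic	II	0
KCND3	c.1649G>A	p.R550H	rs151164490	NA	Uncertain_significance	PM1PM2PP2PP3	Likely_pathogenic	V	0
KCND3	c.325G>C	p.E109Q	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
RYR2	c.356T>C	p.I119T	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
RYR2	c.745T>C	p.S249P	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
RYR2	c.892C>T	p.R298C	rs551099887	NA	Conflicting_interpretations_of_pathogenicity	PM1PM2PP2PP3	Likely_pathogenic	V	0
RYR2	c.1396C>T	p.P466S	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
RYR2	c.1910T>G	p.L637R	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
RYR2	c.1940G>A	p.R647H	rs766330093	NA	Uncertain_significance	PM1PM2PP2PP3	Likely_pathogenic	V	0
RYR2	c.4388G>A	p.R1463H	rs753707154	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	0
RYR2	c.4531G>T	p.V1511L	NA	NA	Uncertain_significance	PM1PM2PP2PP3	Likely_pathogenic	V	0
RYR2	c.6367C>T	p.L2123F	rs1060500159	NA	Uncertain_significance	PM1PM2PP2PP3	Likely_pathogenic	V	0
RYR2	c.11758C>A	p.L3920I	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
RYR2	c.13526T>C	p.V4509A	NA	NA	Uncertain_significance	PM1PM2PP2PP3	Likely_pathogenic	V	0
CAV3	c.244G>T	p.V82F	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
KCNQ1	c.1570G>T	p.V524L	NA	NA	NA	PM1PM2PM5BP4	Likely_pathogenic	IV	1
CACNA1C	c.1914C>A	p.S638R	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	0
CACNA1C	c.2813T>C	p.I938T	rs377165829	NA	Uncertain_significance	PM1PM2PP2PP3	Likely_pathogenic	V	0
CACNA1C	c.2837T>C	p.I946T	rs747728381	NA	Uncertain_significance	PM1PM2PP2PP3	Likely_pathogenic	V	0
CACNA1C	c.3200C>T	p.A1067V	rs750998195	NA	Conflicting_interpretations_of_pathogenicity	PM1PM2PP2PP3	Likely_pathogenic	V	0
CACNA1C	c.3691C>T	p.L1231F	rs766971426	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	0
CACNA1C	c.4819C>T	p.P1607S	rs745938574	NA	Uncertain_significance	PM1PM2PP2PP3	Likely_pathogenic	V	0
CACNA1C	c.5270G>T	p.S1757I	rs753388569	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	0
CACNA1C	c.5684G>A	p.R1895Q	rs753954220	NA	Uncertain_significance	PM2PP2PP3PM1	Likely_pathogenic	V	0
ABCC9	c.2474C>T	p.A825V	rs964127282	NA	Uncertain_significance	PM1PM2PP2PP3	Likely_pathogenic	V	0
ABCC9	c.1318C>G	p.Q440E	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
KCNJ2	c.208G>C	p.A70P	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
KCNJ2	c.817A>G	p.I273V	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
KCNE2	c.131A>G	p.E44G	NA	NA	NA	PM1PM2PP2PP3	Likely_pathogenic	V	1
KCNE2	c.229C>T	p.R77W	rs141423405	No effect on IKr (PMID: 17275752)	Uncertain_significance	PM1PM2PP2PP3BS3	Likely_pathogenic	V	0
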