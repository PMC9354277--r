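# Per-variant heterozygote carrier counts reported for the pathogenic and
# high-confidence likely-pathogenic variants in the 1029-genome cohort.
# Carriers are disjoint across variants; all carriers are heterozygous.
gene	hgvs_c	branch	n_carriers
KCNH2	c.2467C>T	nonsyn	1
SCN5A	c.6046G>A	nonsyn	1
CACNA1C	c.2573G>A	nonsyn	1
KCNE2	c.170T>C	nonsyn	2
KCND3	c.1348C>T	nonsyn	2
KCNE3	c.49G>A	nonsyn	2
SCN3B	c.328G>A	nonsyn	3
CASQ2	c.706G>T	plof	1
CASQ2	c.420+2T>C	plof	1
PKP2	c.1237C>T	plof	1
KCNQ1	c.360del	plof	1
KCNQ1	c.524_534dup	plof	1
TRDN	c.1537C>T	plof	2
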