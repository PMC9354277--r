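# Cardiac ion channelopathy gene panel (36 genes).
# SYNTHETIC RECONSTRUCTION of a published channelopathy panel: gene symbols,
# evidence categories (12 definitive / 2 acquired-LQTS-only / 22 limited or
# disputed), inheritance modes and per-gene mechanism flags were assembled
# from the disease-gene literature (Adler et al. 2020; ClinGen channelopathy
# gene curation) to satisfy the panel's published summary counts. It is a
# curation artifact, not a clinical resource.
# lof_mechanism: loss of function is an established disease mechanism (drives
#   PVS1 for truncating variants and BP1 for missense ones).
# missense_constrained: gene has a low benign-missense rate (drives PP2).
gene	evidence_category	inheritance	lof_mechanism	missense_constrained
KCNQ1	definitive	AD	TRUE	FALSE
KCNH2	definitive	AD	TRUE	FALSE
SCN5A	definitive	AD	FALSE	FALSE
CACNA1C	definitive	AD	FALSE	TRUE
RYR2	definitive	AD	FALSE	TRUE
CASQ2	definitive	AR	TRUE	FALSE
TRDN	definitive	AR	TRUE	FALSE
PKP2	definitive	AD	TRUE	FALSE
KCNJ2	definitive	AD	FALSE	TRUE
CALM1	definitive	AD	FALSE	FALSE
CALM2	definitive	AD	FALSE	FALSE
CALM3	definitive	AD	FALSE	FALSE
KCNE1	acquired_only	AD	FALSE	FALSE
KCNE2	acquired_only	AD	FALSE	TRUE
KCND3	limited_disputed	AD	FALSE	TRUE
KCNE3	limited_disputed	AD	FALSE	FALSE
SCN3B	limited_disputed	AD	FALSE	FALSE
CAV3	limited_disputed	AD	FALSE	TRUE
ABCC9	limited_disputed	AD	FALSE	TRUE
AKAP9	limited_disputed	AD	FALSE	FALSE
ANK2	limited_disputed	AD	FALSE	FALSE
SCN10A	limited_disputed	AD	FALSE	FALSE
TRPM4	limited_disputed	AD	FALSE	FALSE
SCN1B	limited_disputed	AD	FALSE	FALSE
SCN2B	limited_disputed	AD	FALSE	FALSE
SCN4B	limited_disputed	AD	FALSE	FALSE
GPD1L	limited_disputed	AD	FALSE	FALSE
HCN4	limited_disputed	AD	FALSE	FALSE
SNTA1	limited_disputed	AD	FALSE	FALSE
RANGRF	limited_disputed	AD	FALSE	FALSE
SLMAP	limited_disputed	AD	FALSE	FALSE
CACNB2	limited_disputed	AD	FALSE	FALSE
CACNA2D1	limited_disputed	AD	FALSE	FALSE
DPP6	limited_disputed	AD	FALSE	FALSE
KCNJ8	limited_disputed	AD	FALSE	FALSE
TECRL	limited_disputed	AR	FALSE	FALSE
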