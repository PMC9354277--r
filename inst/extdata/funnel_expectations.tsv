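# Genome-scale filtering funnel reported for the 1029-genome cohort over the
# 36-gene panel (reference only; depends on the full cohort callset and is
# not recomputable from shipped data).
stage	n_variants
panel_genes	186782
rare	156351
exonic	1263
nonsynonymous	693
deleterious_not_clinvar_benign	440
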