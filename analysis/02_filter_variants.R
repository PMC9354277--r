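#!/usr/bin/env Rscript

# The nonsynonymous filtering cascade: rare (folded MAF < 0.05 in every
# reference dataset where observed) -> exonic -> missense SNV -> predicted
# deleterious by at least one of SIFT/PolyPhen/CADD -> not ClinVar-benign.
# Writes the funnel table and the surviving variants.

source(file.path("analysis", "00_common.R"))

gen <- default_cohort()
cohort <- read_cohort(gen$vcf, gen$annotations)
res <- run_cascade(cohort$variants, filter_config())

data.table::fwrite(res$funnel$stages, file.path("results", "funnel.tsv"), sep = "\t")
write_variant_table(res$survivors, file.path("results", "nonsyn_survivors.tsv"))

message("filtering funnel:")
for (i in seq_len(nrow(res$funnel$stages))) {
  message(sprintf(
    "  %-20s %4d -> %4d", res$funnel$stages$stage[i],
    res$funnel$stages$n_in[i], res$funnel$stages$n_out[i]
  ))
}
message(nrow(res$survivors), " nonsynonymous survivors")
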