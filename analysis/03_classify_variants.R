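#!/usr/bin/env Rscript

# Loss-of-function calling (HC/LC), ACMG/AMP attribute assignment and
# tiered classification of the merged survivor set. Writes the per-variant
# classification table and a class/band summary.

source(file.path("analysis", "00_common.R"))

gen <- default_cohort()
run <- default_run(gen)

cls <- run$merged[, c(
  "variant_id", "branch", "gene", "hgvs_c", "hgvs_p",
  "attributes", "klass", "tier", "band", "unique"
)]
data.table::fwrite(cls, file.path("results", "classifications.tsv"), sep = "\t", na = "NA")

summary_tab <- dplyr::count(cls, branch, klass, band, name = "n")
data.table::fwrite(summary_tab, file.path("results", "classification_summary.tsv"), sep = "\t")

plp <- cls[cls$band %in% c("pathogenic", "lp_high"), ]
data.table::fwrite(plp, file.path("results", "plp_variants.tsv"), sep = "\t", na = "NA")

message(nrow(run$plof_calls), " high-confidence pLoF calls; ",
  nrow(cls), " classified survivors")
message(
  "bands: ", sum(cls$band == "pathogenic"), " pathogenic, ",
  sum(cls$band == "lp_high"), " LP high-confidence, ",
  sum(cls$band == "lp_low"), " LP low-confidence, ",
  sum(cls$band == "other"), " VUS/likely-benign"
)
message(nrow(plp), " pathogenic / high-confidence LP variants (the screening set)")
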