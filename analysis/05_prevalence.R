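#!/usr/bin/env Rscript

# Carrier counting over the cohort genotypes and genotypic-prevalence
# estimation, overall and restricted to definitive-evidence genes.

source(file.path("analysis", "00_common.R"))

gen <- default_cohort()
run <- default_run(gen)

per_variant <- run$carriers$per_variant[, c(
  "variant_id", "gene", "evidence_category", "inheritance",
  "n_carriers", "n_hom", "ar_het"
)]
data.table::fwrite(per_variant, file.path("results", "carriers.tsv"), sep = "\t")

prev <- list(
  cohort_size = run$carriers$n_cohort,
  bands = run$carriers$bands,
  distinct_carriers = run$carriers$distinct_carriers,
  distinct_carriers_definitive = run$carriers$distinct_definitive,
  all_genes = run$prevalence_all[c("ratio_text", "percent_text")],
  definitive_genes = run$prevalence_definitive[c("ratio_text", "percent_text")]
)
jsonlite::write_json(prev, file.path("results", "prevalence.json"),
  auto_unbox = TRUE, digits = NA, pretty = TRUE
)

message(
  run$carriers$distinct_carriers, " of ", run$carriers$n_cohort,
  " individuals carry a pathogenic / high-confidence LP variant -> ",
  run$prevalence_all$ratio_text, " (", run$prevalence_all$percent_text, ")"
)
message(
  "restricted to definitive-evidence genes: ",
  run$carriers$distinct_definitive, " carriers -> ",
  run$prevalence_definitive$ratio_text, " (",
  run$prevalence_definitive$percent_text, ")"
)
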