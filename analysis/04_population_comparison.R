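#!/usr/bin/env Rscript

# Cross-population allele-frequency comparison (Fisher's exact test on
# allele counts, cohort vs each reference dataset) for the screening set,
# and population-uniqueness bookkeeping for all survivors.

source(file.path("analysis", "00_common.R"))

gen <- default_cohort()
run <- default_run(gen)

data.table::fwrite(run$af_comparisons, file.path("results", "af_comparisons.tsv"),
  sep = "\t", na = "NA"
)

nonsyn <- run$merged[run$merged$branch == "nonsyn", ]
uniq_tab <- report_unique_by_class(nonsyn, nonsyn$unique)
data.table::fwrite(uniq_tab, file.path("results", "unique_by_class.tsv"), sep = "\t")

n_tests <- sum(!is.na(run$af_comparisons$p_value))
message(
  nrow(run$af_comparisons), " dataset comparisons (", n_tests,
  " Fisher tests; references without counts reported AF-only); ",
  sum(run$af_comparisons$significant, na.rm = TRUE),
  " significant at p < 0.05"
)
message(
  sum(run$merged$unique), " population-unique survivors (",
  sum(nonsyn$unique), " nonsynonymous, ",
  sum(run$merged$unique) - sum(nonsyn$unique), " pLoF); ",
  "unique nonsynonymous by class: ",
  paste(sprintf("%s %d (%.1f%%)", uniq_tab$category, uniq_tab$n, uniq_tab$percent),
    collapse = ", "
  )
)
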