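# Shared setup for the analysis drivers: the default synthetic cohort,
# regenerated deterministically (seed lives in the generator spec) under
# scratch/ so every numbered script is independently re-runnable.

library(channelscan)

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

default_cohort <- function() {
  generate_cohort(generator_spec(), dir = file.path("scratch", "cohort"))
}

default_run <- function(gen = default_cohort()) {
  run_pipeline(
    gen$vcf, gen$annotations,
    panel = gen$panel, transcripts = gen$transcripts,
    curated = gen$curated, ref_counts_path = gen$reference_counts
  )
}
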