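Package: channelscan
Title: Cohort-Scale Triage of Cardiac Ion Channelopathy Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Rare-variant triage for cardiac ion channelopathy gene panels at
    population-cohort scale. Implements the full screening pipeline: a
    rare/exonic/nonsynonymous/deleterious/not-ClinVar-benign filtering cascade
    with funnel bookkeeping, a simplified high/low-confidence predicted
    loss-of-function (pLoF) classifier over transcript models, an ACMG/AMP
    evidence-combination engine with tiered Pathogenic and Likely-Pathogenic
    subclasses, cross-population allele-frequency comparison by Fisher's exact
    test, population-uniqueness flagging, and genotypic-prevalence estimation
    with carrier counting over diploid cohort genotypes. A deterministic
    synthetic-cohort generator with a ground-truth book makes every stage
    testable end to end without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    dplyr,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
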