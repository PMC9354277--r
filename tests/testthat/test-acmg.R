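# Evidence parsing, attribute assignment, and the combination engine.

test_that("attribute strings parse on the code grammar and reject junk", {
  expect_equal(parse_acmg("PS3PM2PP2BP4"), c("PS3", "PM2", "PP2", "BP4"))
  expect_equal(parse_acmg("PVS1PM2PP3"), c("PVS1", "PM2", "PP3"))
  expect_equal(parse_acmg(""), character(0))
  expect_equal(parse_acmg(c("PM2", "PM2", "PP3")), c("PM2", "PP3")) # dedupe
  expect_error(parse_acmg("PS3PMX"), "cannot parse")
  expect_error(parse_acmg("PS9"), "unknown ACMG/AMP code")
  expect_error(classify_batch(c("PM2PP3", "PQ1")), "cannot parse|unknown")
})

test_that("published evidence sets combine to their printed class and tier", {
  cases <- tibble::tribble(
    ~evidence, ~klass, ~tier,
    "PS3PM2PP2BP4", "Likely_pathogenic", "II",
    "PVS1PM2PP3PP5", "Pathogenic", "Id",
    "PVS1PM2PP3", "Pathogenic", "Ic",
    "PS3PM1PM2PP3PP5BP1", "Pathogenic", "IIIb",
    "PM1PM2PM5BP4", "Likely_pathogenic", "IV",
    "PM1PM2PP2PP3", "Likely_pathogenic", "V",
    "PS3PM2PP2PP3PP5", "Likely_pathogenic", "II", # 1 PS + 1 PM wins over III
    "PM1PM2PP2PP3BS3", "Likely_pathogenic", "V" # benign code does not veto
  )
  for (i in seq_len(nrow(cases))) {
    got <- acmg_combine(cases$evidence[i])
    expect_equal(got$klass, cases$klass[i], info = cases$evidence[i])
    expect_equal(got$tier, cases$tier[i], info = cases$evidence[i])
  }
})

test_that("strict mode turns benign-conflicted pathogenic-side matches into VUS", {
  conflicted <- acmg_combine("PM1PM2PP2PP3BS3", mode = "strict")
  expect_equal(conflicted$klass, "VUS")
  expect_true(is.na(conflicted$tier))
  # without benign codes the two modes agree
  clean <- "PS3PM1PM2PP3"
  expect_equal(
    acmg_combine(clean, "strict")[c("klass", "tier")],
    acmg_combine(clean, "table_faithful")[c("klass", "tier")]
  )
})

test_that("benign combinations and the empty set classify as stated", {
  expect_equal(acmg_combine(character(0))$klass, "VUS")
  expect_equal(acmg_combine("BA1")$klass, "Benign")
  expect_equal(acmg_combine("BA1PS3PM1PM2")$klass, "Benign") # BA1 stands alone
  expect_equal(acmg_combine("BS1BS3")$klass, "Benign")
  expect_equal(acmg_combine("BS3BP4")$klass, "Likely_benign")
  expect_equal(acmg_combine("BP1BP4")$klass, "Likely_benign")
  expect_equal(acmg_combine("BP4")$klass, "VUS")
  expect_true(is.na(acmg_combine("BP1BP4")$tier)) # tier only for P/LP
})

test_that("exhaustive subset enumeration agrees with the brute-force rule evaluator", {
  pool <- c("PVS1", "PS3", "PM1", "PM2", "PP1", "PP2", "PP3", "PP5")
  for (mask in 0:(2^length(pool) - 1)) {
    codes <- pool[bitwAnd(mask, 2^(seq_along(pool) - 1)) > 0]
    got <- acmg_combine(codes)
    want <- oracle_combine(codes)
    expect_equal(got$klass, want$klass, info = paste(codes, collapse = "+"))
    expect_equal(got$tier, want$tier, info = paste(codes, collapse = "+"))
    # strict and table_faithful agree whenever no benign code is present
    strict <- acmg_combine(codes, mode = "strict")
    expect_equal(strict$klass, got$klass)
  }
  # spot-check the oracle against mixed benign/pathogenic sets too
  mixed <- list(
    c("PS3", "PM2", "BP4"), c("PM1", "PM2", "PM5", "BP4"),
    c("BS3", "BP4"), c("PVS1", "PM2", "PP3", "BS3")
  )
  for (codes in mixed) {
    expect_equal(
      acmg_combine(codes)[c("klass", "tier")],
      oracle_combine(codes)[c("klass", "tier")]
    )
  }
})

test_that("adding pathogenic-side codes never demotes the class (table_faithful)", {
  rank <- c(VUS = 0, Likely_pathogenic = 1, Pathogenic = 2)
  base_sets <- list(
    character(0), "PM2", c("PM1", "PM2"), c("PS3", "PM2"),
    c("PM1", "PM2", "PP2", "PP3"), c("PVS1", "PM2")
  )
  additions <- c("PVS1", "PS1", "PM3", "PP4")
  for (codes in base_sets) {
    before <- acmg_combine(codes)$klass
    for (extra in additions) {
      after <- acmg_combine(union(codes, extra))$klass
      expect_gte(rank[[after]], rank[[before]])
    }
  }
})

test_that("classification bands split LP tiers at III/IV", {
  expect_equal(confidence_band("Pathogenic", "IIIb"), "pathogenic")
  expect_equal(confidence_band("Likely_pathogenic", "II"), "lp_high")
  expect_equal(confidence_band("Likely_pathogenic", "V"), "lp_low")
  expect_equal(confidence_band("VUS"), "other")
  expect_equal(confidence_band("Likely_benign"), "other")
})

test_that("batch classification is deterministic and order-independent", {
  fx <- load_published_fixtures()
  ev <- fx$evidence$attributes
  res <- classify_batch(ev)
  expect_identical(classify_batch(ev), res)
  perm <- sample(length(ev))
  expect_identical(classify_batch(ev[perm])[order(perm), ]$klass, res$klass)
  # duplicate rows classify identically
  dup <- classify_batch(c("PM1PM2PP2PP3", "PM1PM2PP2PP3"))
  expect_identical(dup[1, ], dup[2, ])
})

test_that("attribute assignment reproduces curated evidence sets", {
  panel <- default_gene_panel()
  hotspots <- tibble::tibble(gene = c("KCNH2", "CASQ2"), start = 2400L, end = 2600L)

  # missense with damaging functional evidence, in a hotspot, absent from
  # references, in-silico deleterious, reputable-source pathogenic, in a
  # truncating-mechanism gene
  v1 <- toy_variants(1,
    gene = "KCNH2", pos = 2467L, ref = "C", alt = "T",
    sift_call = "D", polyphen_call = "D", cadd_phred = 25,
    clinvar_sig = "Pathogenic/likely_pathogenic"
  )
  cur <- curated_evidence(
    per_variant = tibble::tibble(
      variant_id = variant_id("chr1", 2467L, "C", "T"),
      functional_effect = "damaging", citation = "PMID:16432067"
    ),
    hotspots = hotspots
  )
  got <- assign_attributes(v1[1, ],
    lof_call = NULL,
    panel_entry = panel[panel$gene == "KCNH2", ], curated = cur
  )
  expect_equal(got, c("PS3", "PM1", "PM2", "PP3", "PP5", "BP1"))

  # HC stopgain in a LoF-mechanism gene, absent from references, CADD-high
  v2 <- toy_variants(1,
    gene = "CASQ2", pos = 706L, ref = "G", alt = "T",
    consequence = "stopgain", cadd_phred = 35
  )
  lof <- grade_confidence(
    list(chrom = "x", pos = 1, ref = "A", alt = "T"),
    toy_transcript(),
    lof_type = "stopgain"
  )
  lof$confidence <- "HC" # force an HC call object
  got2 <- assign_attributes(v2[1, ],
    lof_call = lof,
    panel_entry = panel[panel$gene == "CASQ2", ], curated = curated_evidence()
  )
  expect_equal(got2, c("PVS1", "PM2", "PP3"))

  # no curated evidence, common in gnomAD, benign in-silico
  v3 <- toy_variants(1,
    gene = "SCN10A", af_gnomad_all = 0.2,
    sift_call = "T", polyphen_call = "B", cadd_phred = 3
  )
  got3 <- assign_attributes(v3[1, ],
    panel_entry = panel[panel$gene == "SCN10A", ]
  )
  expect_true(all(grepl("^B", got3))) # benign-side codes only (or none)
})

test_that("curated damaging assertions require a citation", {
  expect_error(
    curated_evidence(per_variant = tibble::tibble(
      variant_id = "x", functional_effect = "damaging", citation = NA_character_
    )),
    "citation"
  )
})
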