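# The five-stage filtering cascade and its funnel bookkeeping.

test_that("the rarity filter folds allele frequency to the minor allele", {
  # hand oracle on boundary values: folded MAF = min(af, 1 - af), strict <
  cases <- tibble::tribble(
    ~af, ~kept,
    0.06, FALSE, # minor allele 0.06 >= 0.05
    0.04, TRUE,
    0.05, FALSE, # boundary: strict inequality
    0.96, TRUE, # folded: min(0.96, 0.04) = 0.04 < 0.05
    0.95, FALSE, # folded: 0.05, not < 0.05
    0.999, TRUE,
    NA, TRUE # absent everywhere = rarest
  )
  v <- toy_variants(nrow(cases), af_gnomad_all = cases$af)
  out <- filter_rare(v, filter_config())
  expect_equal(v$pos %in% out$pos, cases$kept)
})

test_that("rarity requires the MAF condition in every dataset where observed", {
  v <- toy_variants(2,
    af_gnomad_all = c(0.01, 0.01),
    af_1000g_all = c(NA, 0.2)
  )
  out <- filter_rare(v)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, v$pos[1])
})

test_that("an unknown reference dataset in the config fails", {
  expect_error(
    filter_rare(toy_variants(1), filter_config(reference_datasets = "gnomad_v99")),
    "unknown reference dataset"
  )
})

test_that("region and consequence filters keep exonic missense SNVs only", {
  v <- toy_variants(4,
    region = c("exonic", "intronic", "exonic", "splicing"),
    consequence = c("missense", "intronic", "synonymous", "splicing")
  )
  expect_equal(filter_exonic(v)$pos, v$pos[c(1, 3)])
  expect_equal(filter_nonsynonymous(filter_exonic(v))$pos, v$pos[1])
  # stopgain SNVs leave this branch (the pLoF branch handles them)
  sg <- toy_variants(1, consequence = "stopgain")
  expect_equal(nrow(filter_nonsynonymous(sg)), 0)
})

test_that("one affirmative in-silico tool suffices; thresholds are strict", {
  v <- toy_variants(5,
    sift_call = c("T", "T", "D", NA, NA),
    polyphen_call = c("B", "B", "B", "P", NA),
    cadd_phred = c(20, 15, 10, NA, NA)
  )
  out <- filter_deleterious(v)
  expect_equal(out$pos, v$pos[c(1, 3, 4)]) # CADD 15.0 is not > 15; all-absent drops
})

test_that("only ClinVar-benign entries are removed", {
  v <- toy_variants(4, clinvar_sig = c(
    "Benign", "Conflicting_interpretations_of_pathogenicity", NA, "Pathogenic"
  ))
  out <- filter_not_clinvar_benign(v)
  expect_equal(out$pos, v$pos[2:4])
})

test_that("stages are idempotent, monotone subsets, and order-insensitive where independent", {
  gen <- generate_cohort(small_spec(), dir = tempfile("cascade"))
  v <- read_cohort(gen$vcf, gen$annotations)$variants
  cfg <- filter_config()
  for (f in list(
    function(x) filter_rare(x, cfg), filter_exonic, filter_nonsynonymous,
    function(x) filter_deleterious(x, cfg),
    function(x) filter_not_clinvar_benign(x, cfg)
  )) {
    once <- f(v)
    expect_true(nrow(once) <= nrow(v))
    expect_identical(f(once), once) # idempotent
  }
  # deleterious and ClinVar stages read disjoint fields: they commute
  a <- filter_not_clinvar_benign(filter_deleterious(v, cfg), cfg)
  b <- filter_deleterious(filter_not_clinvar_benign(v, cfg), cfg)
  expect_identical(a[order(a$pos), ], b[order(b$pos), ])
  # the surviving set is invariant to input order
  shuffled <- v[rev(seq_len(nrow(v))), ]
  s1 <- run_cascade(v, cfg)$survivors
  s2 <- run_cascade(shuffled, cfg)$survivors
  expect_setequal(
    variant_id(s1$chrom, s1$pos, s1$ref, s1$alt),
    variant_id(s2$chrom, s2$pos, s2$ref, s2$alt)
  )
})

test_that("the funnel matches generator bookkeeping stage by stage", {
  gen <- generate_cohort(small_spec(), dir = tempfile("funnel"))
  v <- read_cohort(gen$vcf, gen$annotations)$variants
  res <- run_cascade(v)
  tr <- gen$truth
  expected <- c(
    sum(tr$t_rare),
    sum(tr$t_rare & tr$t_exonic),
    sum(tr$t_rare & tr$t_exonic & tr$t_nonsyn),
    sum(tr$t_rare & tr$t_exonic & tr$t_nonsyn & tr$t_deleterious),
    sum(tr$t_rare & tr$t_exonic & tr$t_nonsyn & tr$t_deleterious & tr$t_not_benign)
  )
  expect_equal(res$funnel$stages$n_out, expected)
  # chained counts: out of stage k is in of stage k+1
  expect_equal(res$funnel$stages$n_in[-1], res$funnel$stages$n_out[-5])
  # dropped ids partition each stage
  expect_equal(
    lengths(res$funnel$dropped),
    stats::setNames(
      res$funnel$stages$n_in - res$funnel$stages$n_out,
      res$funnel$stages$stage
    )
  )
})

test_that("the default cohort funnel is strictly decreasing; empty input yields zero counts", {
  run <- full_run()
  expect_true(all(diff(c(run$funnel$stages$n_in[1], run$funnel$stages$n_out)) < 0))

  res <- run_cascade(toy_variants(0))
  expect_equal(res$funnel$stages$n_in, rep(0L, 5))
  expect_equal(res$funnel$stages$n_out, rep(0L, 5))
  expect_equal(nrow(res$survivors), 0)
})
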