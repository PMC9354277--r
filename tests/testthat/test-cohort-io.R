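# Variant data model, VCF + annotation join, table round-trips, gene panel.

write_toy_vcf <- function(path, records, samples = c("S1", "S2")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

toy_annotation <- function(path, df) {
  write_variant_table(df, path)
  path
}

test_that("VCF records join their annotation rows key-exactly", {
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t200\trs1\tC\tT\t.\tPASS\t.\tGT\t1/1\t0/1",
    "chr2\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0/0\t0/1"
  ))
  ann <- toy_variants(3,
    chrom = c("chr1", "chr1", "chr2"),
    pos = c(100L, 200L, 300L),
    ref = c("A", "C", "G"), alt = c("G", "T", "A"),
    gene = c("KCNQ1", "KCNH2", "SCN5A")
  )
  res <- read_cohort(vcf, toy_annotation(tempfile(fileext = ".tsv"), ann))
  expect_equal(nrow(res$variants), 3)
  expect_equal(res$variants$gene, c("KCNQ1", "KCNH2", "SCN5A"))
  expect_equal(unname(res$genotypes$zygosity[, "S1"]), c(1L, 2L, 0L))

  # permuting annotation rows never changes the joined output
  res2 <- read_cohort(vcf, toy_annotation(tempfile(fileext = ".tsv"), ann[c(3, 1, 2), ]))
  expect_identical(res$variants, res2$variants)
})

test_that("multiallelic records decompose into one row per ALT, conserving allele counts", {
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t1/2\t0/1"
  ))
  ann <- toy_variants(2,
    pos = c(100L, 100L), ref = c("A", "A"), alt = c("G", "T")
  )
  res <- suppressWarnings(read_cohort(vcf, toy_annotation(tempfile(fileext = ".tsv"), ann)))
  expect_equal(nrow(res$variants), 2)
  expect_equal(res$variants$alt, c("G", "T"))
  # S1 is 1/2: one allele each; S2 is 0/1: one G allele
  expect_equal(unname(cohort_ac(res$genotypes)), c(2, 1))
  # total decomposed ALT count equals the record's non-reference allele count
  expect_equal(sum(cohort_ac(res$genotypes)), 3)
})

test_that("missing annotation rows warn and are retained with absent annotations", {
  vcf <- write_toy_vcf(tempfile(fileext = ".vcf"), c(
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t900\t.\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/1"
  ))
  ann <- toy_variants(1, pos = 100L)
  expect_warning(
    res <- read_cohort(vcf, toy_annotation(tempfile(fileext = ".tsv"), ann)),
    "without an annotation row"
  )
  expect_equal(nrow(res$variants), 2)
  expect_true(is.na(res$variants$gene[2]))
})

test_that("malformed VCF fails naming the file", {
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("this is", "not a VCF"), bad)
  expect_error(
    read_cohort(bad, toy_annotation(tempfile(fileext = ".tsv"), toy_variants(1))),
    "malformed VCF"
  )
})

test_that("variant tables round-trip losslessly, including empty tables", {
  df <- toy_variants(3,
    cadd_phred = c(12.5, NA, 31.02),
    sift_call = c("D", NA, "T"),
    af_gnomad_all = c(NA, 0.0123, 1e-5),
    in_literature = c(TRUE, FALSE, NA)
  )
  path <- tempfile(fileext = ".tsv")
  write_variant_table(df, path)
  back <- read_variant_table(path)
  expect_equal(as.data.frame(back[, names(df)]), as.data.frame(df))

  empty <- df[0, ]
  p2 <- tempfile(fileext = ".tsv")
  write_variant_table(empty, p2)
  expect_equal(nrow(read_variant_table(p2)), 0)
  expect_equal(length(readLines(p2)), 1) # header only
})

test_that("a generated cohort round-trips read -> write -> read unchanged", {
  gen <- generate_cohort(small_spec(), dir = tempfile("rt"))
  first <- read_cohort(gen$vcf, gen$annotations)
  rewritten <- tempfile(fileext = ".tsv")
  write_variant_table(first$variants, rewritten)
  second <- read_cohort(gen$vcf, rewritten)
  expect_equal(
    as.data.frame(second$variants[, names(first$variants)]),
    as.data.frame(first$variants)
  )
  expect_identical(first$genotypes$zygosity, second$genotypes$zygosity)
})

test_that("variant validation enforces the data-model invariants", {
  expect_error(validate_variants(toy_variants(1, pos = 0L)), "positions")
  expect_error(validate_variants(toy_variants(1, alt = "A")), "differ")
  expect_error(validate_variants(toy_variants(1, af_gnomad_all = 1.2)), "outside")
  bad <- toy_variants(1, af_gnomad_all = 0.5, ac_gnomad_all = 10, an_gnomad_all = 100)
  expect_error(validate_variants(bad), "ac/an")
  ok <- toy_variants(1, af_gnomad_all = 0.1, ac_gnomad_all = 10, an_gnomad_all = 100)
  expect_silent(validate_variants(ok))
})

test_that("the default gene panel has 36 genes, 12 definitive", {
  panel <- default_gene_panel()
  expect_equal(nrow(panel), 36)
  expect_equal(sum(panel$evidence_category == "definitive"), 12)
  expect_true(all(c("KCNQ1", "KCNH2", "SCN5A", "CASQ2", "TRDN", "PKP2") %in%
    panel$gene[panel$evidence_category == "definitive"]))
})

test_that("panel validation rejects duplicates and unknown categories", {
  panel <- default_gene_panel()
  dup <- rbind(panel, panel[panel$gene == "KCNQ1", ])
  p <- tempfile(fileext = ".tsv")
  data.table::fwrite(dup, p, sep = "\t")
  expect_error(load_gene_panel(p), "duplicated gene symbol.*KCNQ1")

  bad <- panel
  bad$evidence_category[1] <- "very_strong"
  p2 <- tempfile(fileext = ".tsv")
  data.table::fwrite(bad, p2, sep = "\t")
  expect_error(load_gene_panel(p2), "unknown evidence_category.*very_strong")
})
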