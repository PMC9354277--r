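# pLoF type calling and HC/LC confidence grading on toy transcripts whose
# CDS reads GAA at every codon (G>T at a codon start plants a TAA stop).

toy_var <- function(tx, pos, ref, alt, consequence = NA_character_) {
  list(chrom = tx$chrom, pos = pos, ref = ref, alt = alt, consequence = consequence)
}

test_that("substitutions creating a stop codon mid-CDS are HC stopgains", {
  tx <- toy_transcript()
  p <- tx$exon_starts[1] + 3L # codon 2, position 1
  expect_equal(call_lof_type(toy_var(tx, p, "G", "T"), tx), "stopgain")
  call <- grade_confidence(toy_var(tx, p, "G", "T"), tx)
  expect_equal(call$confidence, "HC")
  # a substitution not creating a stop is no LoF
  expect_equal(call_lof_type(toy_var(tx, p, "G", "C"), tx), "none")
})

test_that("indel frame arithmetic decides frameshift vs in-frame", {
  tx <- toy_transcript()
  p <- tx$exon_starts[1] + 6L # codon 3 start
  # 1-bp deletion: frameshift
  expect_equal(call_lof_type(toy_var(tx, p, "GA", "G"), tx), "frameshift")
  # 11-bp duplication: frameshift (matches the G179Sfs*62-style event)
  ins <- paste0("G", strrep("GAA", 3), "GA")
  expect_equal(nchar(ins) - 1L, 11L)
  expect_equal(call_lof_type(toy_var(tx, p, "G", ins), tx), "frameshift")
  # in-frame 3-bp deletion: none
  expect_equal(call_lof_type(toy_var(tx, p, "GAAG", "G"), tx), "none")
})

test_that("intronic +2 substitutions are canonical splice sites (c.420+2-style)", {
  tx <- toy_transcript()
  donor2 <- tx$exon_ends[1] + 2L
  v <- toy_var(tx, donor2, "T", "C")
  expect_equal(call_lof_type(v, tx), "splice_site")
  expect_equal(grade_confidence(v, tx)$confidence, "HC")
  # +3 is outside the default window: not pLoF at all
  expect_equal(call_lof_type(toy_var(tx, donor2 + 1L, "T", "C"), tx), "none")
  # acceptor -1 (last intron base) is canonical too
  acceptor1 <- tx$exon_starts[2] - 1L
  expect_equal(call_lof_type(toy_var(tx, acceptor1, "T", "C"), tx), "splice_site")
})

test_that("a widened splice window grades non-canonical positions LC, never HC", {
  tx <- toy_transcript()
  for (off in 1:8) {
    p <- tx$exon_ends[1] + off
    call <- grade_confidence(toy_var(tx, p, "T", "C"), tx, splice_window = 8)
    expect_equal(call$lof_type, "splice_site")
    expect_equal(call$confidence, if (off <= 2) "HC" else "LC")
    if (off > 2) expect_true("non_canonical_splice_position" %in% call$reasons)
  }
})

test_that("NMD-escape truncations and non-canonical transcripts are LC", {
  tx <- toy_transcript()
  # stopgain in the last exon
  p_last <- tx$exon_starts[3] + 9L # codon 24 start (exon 3)
  call <- grade_confidence(toy_var(tx, p_last, "G", "T"), tx)
  expect_equal(call$lof_type, "stopgain")
  expect_equal(call$confidence, "LC")
  expect_true("last_exon" %in% call$reasons)
  # frameshift within 50 bp upstream of the final junction (toy exon 2 is
  # 30 bp, so all of exon 2 is inside the window)
  p_near <- tx$exon_starts[2] + 3L
  call2 <- grade_confidence(toy_var(tx, p_near, "GA", "G"), tx)
  expect_equal(call2$confidence, "LC")
  expect_true("final_junction_50bp" %in% call2$reasons)
  # same mid-CDS stopgain on a non-canonical transcript
  tx_nc <- toy_transcript(canonical = FALSE)
  p <- tx_nc$exon_starts[1] + 3L
  call3 <- grade_confidence(toy_var(tx_nc, p, "G", "T"), tx_nc)
  expect_equal(call3$confidence, "LC")
  expect_true("non_canonical_transcript" %in% call3$reasons)
})

test_that("rule-table enumeration: confidence agrees with the three LC rules", {
  for (canonical in c(TRUE, FALSE)) {
    tx <- toy_transcript(canonical = canonical)
    cases <- list(
      list(pos = tx$exon_starts[1] + 3L, nmd = FALSE), # mid-CDS exon 1
      list(pos = tx$exon_starts[2] + 3L, nmd = TRUE), # junction window
      list(pos = tx$exon_starts[3] + 9L, nmd = TRUE) # last exon
    )
    for (cs in cases) {
      call <- grade_confidence(toy_var(tx, cs$pos, "G", "T"), tx)
      expect_equal(call$lof_type, "stopgain")
      expected <- if (!canonical || cs$nmd) "LC" else "HC"
      expect_equal(call$confidence, expected)
    }
    for (off in c(1L, 2L)) { # canonical splice positions
      call <- grade_confidence(toy_var(tx, tx$exon_ends[1] + off, "T", "C"), tx)
      expected <- if (!canonical) "LC" else "HC"
      expect_equal(call$confidence, expected)
    }
  }
})

test_that("calls are strand-correct under locus mirroring", {
  tx_plus <- toy_transcript(strand = "+")
  span <- c(min(tx_plus$exon_starts), max(tx_plus$exon_ends))
  mirror <- function(p) span[1] + span[2] - p
  comp <- function(b) chartr("ACGT", "TGCA", b)
  seq_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx_plus$seq)))
  tx_minus <- transcript_model(
    tx_id = "TX_TOY_RC", gene = "TOY", chrom = tx_plus$chrom, strand = "-",
    exon_starts = sort(mirror(tx_plus$exon_ends)),
    exon_ends = sort(mirror(tx_plus$exon_starts)),
    cds_start = mirror(tx_plus$cds_end), cds_end = mirror(tx_plus$cds_start),
    canonical = TRUE, seq = seq_rc, seq_offset = span[1]
  )
  probes <- list(
    list(pos = tx_plus$exon_starts[1] + 3L, ref = "G", alt = "T"), # stopgain
    list(pos = tx_plus$exon_starts[1] + 3L, ref = "G", alt = "C"), # none
    list(pos = tx_plus$exon_ends[1] + 2L, ref = "T", alt = "C") # splice
  )
  for (pr in probes) {
    plus_call <- call_lof_type(toy_var(tx_plus, pr$pos, pr$ref, pr$alt), tx_plus)
    minus_call <- call_lof_type(
      toy_var(tx_minus, mirror(pr$pos), comp(pr$ref), comp(pr$alt)), tx_minus
    )
    expect_equal(minus_call, plus_call)
  }
})

test_that("collect_plof recovers the planted HC mix and excludes LC calls", {
  gen <- full_cohort()
  v <- read_cohort(gen$vcf, gen$annotations)$variants
  calls <- collect_plof(v, gen$panel, gen$transcripts)
  expect_equal(nrow(calls), 30)
  expect_equal(
    as.vector(table(factor(calls$lof_type, c("splice_site", "stopgain", "frameshift")))),
    c(10, 11, 9)
  )
  expect_true(all(calls$confidence == "HC"))
  # the planted LC truncations are excluded
  lc <- gen$truth$variant_id[gen$truth$t_lof_confidence == "LC"]
  expect_length(lc, 3)
  expect_length(intersect(lc, calls$variant_id), 0)
  # but they are LoF calls, just low confidence
  all_calls <- collect_plof(v, gen$panel, gen$transcripts, confidence = c("HC", "LC"))
  expect_true(all(lc %in% all_calls$variant_id))
})

test_that("panel genes with LoF variants but no transcript model are skipped with a warning", {
  gen <- generate_cohort(small_spec(), dir = tempfile("plofwarn"))
  v <- read_cohort(gen$vcf, gen$annotations)$variants
  txs <- gen$transcripts
  dropped_gene <- names(txs)[1]
  expect_warning(
    calls <- collect_plof(v, gen$panel, txs[-1]),
    paste0("no transcript model for panel gene ", dropped_gene)
  )
  expect_false(dropped_gene %in% calls$gene)
})

test_that("transcript models round-trip through GFF3", {
  skip_if_not_installed("rtracklayer")
  gen <- generate_cohort(small_spec(), dir = tempfile("gff"))
  back <- read_transcript_models(gen$transcripts_gff)
  expect_setequal(names(back), names(gen$transcripts))
  for (g in names(back)) {
    orig <- gen$transcripts[[g]]
    got <- back[[g]]
    expect_equal(got$exon_starts, orig$exon_starts, info = g)
    expect_equal(got$exon_ends, orig$exon_ends, info = g)
    expect_equal(got$cds_start, orig$cds_start, info = g)
    expect_equal(got$cds_end, orig$cds_end, info = g)
    expect_equal(got$strand, orig$strand, info = g)
    expect_equal(got$canonical, orig$canonical, info = g)
  }
})

test_that("cohorts with no LoF variants yield an empty call set", {
  v <- toy_variants(3)
  calls <- collect_plof(v, default_gene_panel(), list(KCNQ1 = toy_transcript()))
  expect_equal(nrow(calls), 0)
})
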