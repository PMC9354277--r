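# Shared fixtures. The full-size cohort and its pipeline run are generated
# once per test session and reused across files.

.cache <- new.env(parent = emptyenv())

full_cohort <- function() {
  if (is.null(.cache$gen)) {
    .cache$gen <- generate_cohort(
      generator_spec(),
      dir = file.path(tempdir(), "channelscan-full-cohort")
    )
  }
  .cache$gen
}

full_run <- function() {
  if (is.null(.cache$run)) {
    gen <- full_cohort()
    .cache$run <- run_pipeline(
      gen$vcf, gen$annotations,
      panel = gen$panel, transcripts = gen$transcripts,
      curated = gen$curated, ref_counts_path = gen$reference_counts
    )
  }
  .cache$run
}

small_spec <- function(seed = 7L) {
  generator_spec(
    n_samples = 60,
    n_common = 6, n_intronic = 5, n_synonymous = 4,
    n_benign_predicted = 3, n_clinvar_benign = 2,
    n_vus = 20, n_vus_unique = 6,
    n_lb = 5, n_lb_unique = 2,
    n_hc_splice = 2, n_hc_stopgain = 4, n_hc_frameshift = 3,
    n_lc = 1, n_plof_vus_unique = 1,
    plant_plp = TRUE, seed = seed
  )
}

# Minimal annotated variant table builder for unit tests.
toy_variants <- function(n = 1, ...) {
  base <- tibble::tibble(
    chrom = rep("chr1", n),
    pos = seq_len(n) * 100L,
    ref = rep("A", n),
    alt = rep("G", n),
    gene = rep("KCNQ1", n),
    transcript = NA_character_,
    consequence = rep("missense", n),
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    dbsnp_id = NA_character_,
    region = rep("exonic", n),
    sift_call = NA_character_, polyphen_call = NA_character_,
    cadd_phred = NA_real_, clinvar_sig = NA_character_,
    in_literature = FALSE,
    af_1000g_all = NA_real_, af_gnomad_all = NA_real_, af_esp6500_all = NA_real_
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# A three-exon toy transcript whose CDS reads GAA GAA GAA ... in transcript
# orientation (so a G>T at any codon start plants a TAA stop). Introns are
# filled with a fixed non-coding pattern.
toy_transcript <- function(strand = "+", canonical = TRUE,
                           chrom = "chr1", start = 1001L,
                           exon_len = 30L, intron_len = 10L, n_exons = 3L) {
  starts <- start + (exon_len + intron_len) * (seq_len(n_exons) - 1L)
  ends <- starts + exon_len - 1L
  tx <- transcript_model(
    tx_id = "TX_TOY", gene = "TOY", chrom = chrom, strand = strand,
    exon_starts = starts, exon_ends = ends,
    cds_start = starts[1], cds_end = ends[n_exons],
    canonical = canonical,
    seq = strrep("T", ends[n_exons] - starts[1] + 1L),
    seq_offset = starts[1]
  )
  n_codons <- (exon_len * n_exons) %/% 3L
  for (k in seq_len(n_codons)) tx <- channelscan:::set_codon(tx, k, "GAA")
  tx
}

# Independent brute-force evaluator of the ACMG/AMP combining table, used
# as the enumeration oracle against acmg_combine(). Collects every matching
# sub-rule and resolves by an explicit priority list.
oracle_combine <- function(codes, mode = "table_faithful") {
  pvs <- "PVS1" %in% codes
  ps <- length(grep("^PS[1-4]$", codes))
  pm <- length(grep("^PM[1-6]$", codes))
  pp <- length(grep("^PP[1-5]$", codes))
  ba <- "BA1" %in% codes
  bs <- length(grep("^BS[1-4]$", codes))
  bp <- length(grep("^BP[1-7]$", codes))
  if (ba) {
    return(list(klass = "Benign", tier = NA_character_))
  }
  hits <- character(0)
  if (pvs && ps >= 1) hits <- c(hits, "P.Ia")
  if (pvs && pm >= 2) hits <- c(hits, "P.Ib")
  if (pvs && pp >= 2) hits <- c(hits, "P.Id")
  if (pvs && pm >= 1 && pp >= 1) hits <- c(hits, "P.Ic")
  if (ps >= 2) hits <- c(hits, "P.II")
  if (ps >= 1 && pm >= 3) hits <- c(hits, "P.IIIa")
  if (ps >= 1 && pm >= 2 && pp >= 2) hits <- c(hits, "P.IIIb")
  if (ps >= 1 && pm >= 1 && pp >= 4) hits <- c(hits, "P.IIIc")
  if (pvs && pm >= 1) hits <- c(hits, "LP.I")
  if (ps >= 1 && pm >= 1 && pm <= 2) hits <- c(hits, "LP.II")
  if (ps >= 1 && pp >= 2) hits <- c(hits, "LP.III")
  if (pm >= 3) hits <- c(hits, "LP.IV")
  if (pm >= 2 && pp >= 2) hits <- c(hits, "LP.V")
  if (pm >= 1 && pp >= 4) hits <- c(hits, "LP.VI")
  priority <- c(
    "P.Ia", "P.Ib", "P.Id", "P.Ic", "P.II", "P.IIIa", "P.IIIb", "P.IIIc",
    "LP.I", "LP.II", "LP.III", "LP.IV", "LP.V", "LP.VI"
  )
  hit <- priority[priority %in% hits][1]
  if (!is.na(hit)) {
    if (mode == "strict" && (bs > 0 || bp > 0)) {
      return(list(klass = "VUS", tier = NA_character_))
    }
    parts <- strsplit(hit, ".", fixed = TRUE)[[1]]
    klass <- if (parts[1] == "P") "Pathogenic" else "Likely_pathogenic"
    return(list(klass = klass, tier = parts[2]))
  }
  if (bs >= 2) {
    return(list(klass = "Benign", tier = NA_character_))
  }
  if ((bs >= 1 && bp >= 1) || bp >= 2) {
    return(list(klass = "Likely_benign", tier = NA_character_))
  }
  list(klass = "VUS", tier = NA_character_)
}

# Brute-force two-sided Fisher p-value by explicit enumeration over all
# tables with the observed margins, using binomial-coefficient arithmetic.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  c1 <- a + c
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  prob <- function(x) {
    exp(
      lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
    )
  }
  probs <- vapply(xs, prob, numeric(1))
  p0 <- prob(a)
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}
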