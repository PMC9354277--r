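# Deterministic synthetic-cohort generator. Emits a diploid cohort (VCF +
# annotation table + reference-count table + curated evidence) whose
# statistical structure matches the study conditions the pipeline assumes:
# a 1029-sample cohort over the 36-gene panel, planted variants with one
# truth label per filtering stage, a pLoF mix of 10 splice / 11 stopgain /
# 9 frameshift high-confidence calls, the published pathogenic /
# likely-pathogenic attribute sets with exact heterozygous carrier counts
# (1,1,1,2,2,2,3 nonsynonymous; 1,1,1,1,1,2 pLoF; disjoint carriers), and
# the published uniqueness fractions (114 of 440 nonsynonymous, 10 of 30
# pLoF). Genotypes are Hardy-Weinberg binomial at the planted cohort
# frequency except for planted-carrier variants, which receive exact
# counts. Everything is reproducible bit for bit under the spec seed.

PLOF_PATHOGENIC_GENES <- c("CASQ2", "TRDN", "PKP2", "KCNQ1")
PLOF_VUS_GENES <- c(
  "SCN5A", "ANK2", "AKAP9", "SCN10A", "TRPM4",
  "HCN4", "DPP6", "SLMAP", "CACNB2", "SCN1B"
)
VUS_HOT_GENES <- c("AKAP9", "ANK2", "RYR2", "SCN10A", "SCN5A", "TRPM4")
MINUS_STRAND_GENES <- c("PKP2", "ANK2", "HCN4")
REF_AF_DATASETS <- c("1000g_all", "gnomad_all", "esp6500_all", "gnomad_sas", "gme")

#' Synthetic-cohort generator specification
#'
#' The defaults are the study conditions the pipeline is meant for: a
#' 1029-sample diploid cohort with 440 nonsynonymous cascade survivors
#' (the 36 published P/LP attribute sets, 16 likely benign, 388 VUS), a
#' 30-variant high-confidence pLoF set (10 splice / 11 stopgain / 9
#' frameshift, 6 pathogenic), planted failures for every cascade stage,
#' and the published uniqueness fractions and carrier counts.
#'
#' @param n_samples cohort size (diploid individuals).
#' @param n_common,n_intronic,n_synonymous,n_benign_predicted,n_clinvar_benign
#'   planted failures for (respectively) the rarity, exonic,
#'   nonsynonymous, deleteriousness and ClinVar stages.
#' @param n_vus,n_vus_unique nonsynonymous survivors classified VUS, and
#'   how many of them are population-unique.
#' @param n_lb,n_lb_unique likely-benign survivors and unique subset.
#' @param n_hc_splice,n_hc_stopgain,n_hc_frameshift high-confidence pLoF
#'   mix (includes the 6 published pathogenic rows when `plant_plp`).
#' @param n_lc planted low-confidence LoF variants (NMD-escape cases).
#' @param n_plof_vus_unique unique variants among the non-pathogenic HC
#'   pLoF set.
#' @param plant_plp plant the published 36 + 6 P/LP variants with their
#'   attribute sets and exact carrier counts.
#' @param ref_an reference-dataset allele numbers used when emitting counts.
#' @param rare_af_range,common_af_range,pm2_af_range,cohort_af_range allele
#'   frequency ranges for (observed-rare, common, ultra-rare/PM2, cohort
#'   background) draws.
#' @param seed integer seed; the same spec always generates byte-identical
#'   outputs.
#' @return a validated `generator_spec` list.
#' @export
generator_spec <- function(n_samples = 1029,
                           n_common = 60, n_intronic = 50, n_synonymous = 40,
                           n_benign_predicted = 30, n_clinvar_benign = 20,
                           n_vus = 388, n_vus_unique = 98,
                           n_lb = 16, n_lb_unique = 4,
                           n_hc_splice = 10, n_hc_stopgain = 11, n_hc_frameshift = 9,
                           n_lc = 3,
                           n_plof_vus_unique = 8,
                           plant_plp = TRUE,
                           ref_an = c(
                             "1000g_all" = 5008, gnomad_all = 251496,
                             gnomad_sas = 30616, gme = 1984
                           ),
                           rare_af_range = c(5e-4, 0.04),
                           common_af_range = c(0.06, 0.45),
                           pm2_af_range = c(2e-6, 8e-5),
                           cohort_af_range = c(5e-4, 5e-3),
                           seed = 1729L) {
  spec <- list(
    n_samples = as.integer(n_samples),
    n_common = n_common, n_intronic = n_intronic, n_synonymous = n_synonymous,
    n_benign_predicted = n_benign_predicted, n_clinvar_benign = n_clinvar_benign,
    n_vus = n_vus, n_vus_unique = n_vus_unique,
    n_lb = n_lb, n_lb_unique = n_lb_unique,
    n_hc_splice = n_hc_splice, n_hc_stopgain = n_hc_stopgain,
    n_hc_frameshift = n_hc_frameshift,
    n_lc = n_lc, n_plof_vus_unique = n_plof_vus_unique,
    plant_plp = isTRUE(plant_plp),
    ref_an = ref_an,
    rare_af_range = rare_af_range, common_af_range = common_af_range,
    pm2_af_range = pm2_af_range, cohort_af_range = cohort_af_range,
    seed = as.integer(seed)
  )
  validate_generator_spec(spec)
  structure(spec, class = "generator_spec")
}

validate_generator_spec <- function(spec) {
  counts <- unlist(spec[c(
    "n_common", "n_intronic", "n_synonymous", "n_benign_predicted",
    "n_clinvar_benign", "n_vus", "n_vus_unique", "n_lb", "n_lb_unique",
    "n_hc_splice", "n_hc_stopgain", "n_hc_frameshift", "n_lc",
    "n_plof_vus_unique"
  )])
  if (any(counts < 0)) stop("inconsistent spec: negative planted count")
  if (spec$n_vus_unique > spec$n_vus) {
    stop("inconsistent spec: n_vus_unique exceeds n_vus")
  }
  if (spec$n_lb_unique > spec$n_lb) {
    stop("inconsistent spec: n_lb_unique exceeds n_lb")
  }
  n_hc <- spec$n_hc_splice + spec$n_hc_stopgain + spec$n_hc_frameshift
  if (spec$plant_plp) {
    if (spec$n_samples < 19) {
      stop("inconsistent spec: planted carriers need at least 19 samples")
    }
    if (spec$n_hc_splice < 1 || spec$n_hc_stopgain < 3 || spec$n_hc_frameshift < 2) {
      stop(
        "inconsistent spec: the published pathogenic pLoF set needs at least ",
        "1 splice, 3 stopgain and 2 frameshift high-confidence slots"
      )
    }
    if (spec$n_plof_vus_unique > n_hc - 6) {
      stop("inconsistent spec: n_plof_vus_unique exceeds the non-pathogenic HC pLoF count")
    }
  } else if (spec$n_plof_vus_unique > n_hc) {
    stop("inconsistent spec: n_plof_vus_unique exceeds the HC pLoF count")
  }
  invisible(spec)
}

# --- internal helpers -------------------------------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Per-gene synthetic loci: one contig region per gene, cursors for ordinary
# positions (outside any transcript) and hotspot positions.
gene_loci <- function(panel) {
  n <- nrow(panel)
  tibble::tibble(
    gene = panel$gene,
    gidx = seq_len(n),
    chrom = paste0("chr", (seq_len(n) - 1L) %% 22L + 1L),
    base = 1000000L * seq_len(n)
  )
}

make_locus_env <- function(loci) {
  e <- new.env(parent = emptyenv())
  e$plain <- stats::setNames(loci$base + 700000L, loci$gene)
  e$hot <- stats::setNames(loci$base + 800000L, loci$gene)
  e
}

next_plain_pos <- function(env, gene) {
  p <- env$plain[[gene]]
  env$plain[[gene]] <- p + 50L
  p
}

next_hotspot_pos <- function(env, gene) {
  p <- env$hot[[gene]]
  env$hot[[gene]] <- p + 50L
  p
}

# A three-exon, plus- or minus-strand transcript with 300-codon CDS and a
# random genomic sequence attached.
synth_transcript <- function(gene, chrom, base) {
  exon_len <- 300L
  intron_len <- 200L
  start <- base + 1001L
  starts <- start + c(0L, exon_len + intron_len, 2L * (exon_len + intron_len))
  ends <- starts + exon_len - 1L
  strand <- if (gene %in% MINUS_STRAND_GENES) "-" else "+"
  transcript_model(
    tx_id = paste0("TX_", gene), gene = gene, chrom = chrom, strand = strand,
    exon_starts = starts, exon_ends = ends,
    cds_start = starts[1], cds_end = ends[3],
    canonical = TRUE,
    seq = random_dna(ends[3] - starts[1] + 1L), seq_offset = starts[1]
  )
}

set_seq_base <- function(tx, pos, base_plus) {
  i <- pos - tx$seq_offset + 1L
  substr(tx$seq, i, i) <- base_plus
  tx
}

# Overwrite the codon at CDS codon index `codon` (transcript orientation)
# with `codon_tx` (e.g. "GAA"); returns the updated transcript.
set_codon <- function(tx, codon, codon_tx) {
  cdsp <- cds_positions(tx)
  idx <- (codon - 1L) * 3L + 1:3
  bases <- strsplit(codon_tx, "")[[1]]
  for (j in 1:3) {
    b <- if (tx$strand == "-") complement_base(bases[j]) else bases[j]
    tx <- set_seq_base(tx, cdsp[idx[j]], b)
  }
  tx
}

# Planting primitives: each returns list(tx = updated transcript,
# pos/ref/alt of the variant in plus-strand VCF convention).
plant_stopgain <- function(tx, codon) {
  tx <- set_codon(tx, codon, "GAA") # Glu; G>T at base 1 gives the TAA stop
  cdsp <- cds_positions(tx)
  p <- cdsp[(codon - 1L) * 3L + 1L]
  if (tx$strand == "-") {
    list(tx = tx, pos = p, ref = "C", alt = "A")
  } else {
    list(tx = tx, pos = p, ref = "G", alt = "T")
  }
}

plant_frameshift <- function(tx, codon, kind = c("del", "dup")) {
  kind <- match.arg(kind)
  cdsp <- cds_positions(tx)
  p <- sort(cdsp[(codon - 1L) * 3L + 1:3])[1]
  if (kind == "del") {
    ref <- paste0(genomic_base(tx, p), genomic_base(tx, p + 1L))
    list(tx = tx, pos = p, ref = ref, alt = substr(ref, 1, 1))
  } else {
    anchor <- genomic_base(tx, p)
    ins <- random_dna(11L)
    list(tx = tx, pos = p, ref = anchor, alt = paste0(anchor, ins))
  }
}

plant_splice <- function(tx, intron = 1L, offset = 2L) {
  introns <- tx_introns(tx)
  p <- introns$start[intron] + offset - 1L
  ref <- genomic_base(tx, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  list(tx = tx, pos = p, ref = ref, alt = alt)
}

random_snv <- function() {
  ref <- sample(c("A", "C", "G", "T"), 1)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
  c(ref, alt)
}

parse_snv_hgvs <- function(hgvs_c) {
  m <- regmatches(hgvs_c, regexec("([ACGT])>([ACGT])$", hgvs_c))[[1]]
  if (length(m) == 3) m[2:3] else random_snv()
}

# --- the generator ----------------------------------------------------------

#' Generate a synthetic cohort with ground truth
#'
#' Writes a multi-sample VCF, a matching annotation table, a
#' reference-counts table for allele-frequency comparisons, curated
#' evidence tables (functional assertions, hotspot intervals), a GFF3 of
#' the synthetic transcript models, and a truth book recording every
#' variant's intended label at every pipeline stage. Deterministic:
#' the same spec (including its seed) produces byte-identical files.
#'
#' @param spec a [generator_spec()].
#' @param dir output directory (created if needed).
#' @return list with file paths (`vcf`, `annotations`, `reference_counts`,
#'   `truthbook`, `curated_variants`, `hotspots`, `transcripts_gff`), the
#'   in-memory `truth` tibble, `transcripts` models (with sequences),
#'   `curated` evidence, `genotypes`, and the `panel` used.
#' @export
generate_cohort <- function(spec = generator_spec(), dir = tempfile("cohort")) {
  validate_generator_spec(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel <- default_gene_panel()
  loci <- gene_loci(panel)
  withr::with_seed(spec$seed, generate_cohort_impl(spec, dir, panel, loci))
}

generate_cohort_impl <- function(spec, dir, panel, loci) {
  env <- make_locus_env(loci)
  locus <- function(g) loci[loci$gene == g, , drop = FALSE]
  fixtures <- if (spec$plant_plp) load_published_fixtures() else NULL
  rs_counter <- 0L
  next_rs <- function() {
    rs_counter <<- rs_counter + 1L
    sprintf("rs9%06d", rs_counter)
  }
  rows <- list()
  curated_rows <- list()
  draw <- function(range) signif(stats::runif(1, range[1], range[2]), 6)

  blank_row <- function() {
    r <- list(
      chrom = NA_character_, pos = NA_integer_, ref = NA_character_,
      alt = NA_character_, gene = NA_character_, transcript = NA_character_,
      consequence = NA_character_, hgvs_c = NA_character_, hgvs_p = NA_character_,
      dbsnp_id = NA_character_, region = NA_character_,
      sift_call = NA_character_, polyphen_call = NA_character_,
      cadd_phred = NA_real_, clinvar_sig = NA_character_, in_literature = FALSE
    )
    for (ds in REF_AF_DATASETS) r[[paste0("af_", ds)]] <- NA_real_
    r$ac_gnomad_all <- NA_real_
    r$an_gnomad_all <- NA_real_
    # truth labels
    r$t_branch <- "none"
    r$t_rare <- TRUE
    r$t_exonic <- FALSE
    r$t_nonsyn <- FALSE
    r$t_deleterious <- FALSE
    r$t_not_benign <- TRUE
    r$t_survivor_nonsyn <- FALSE
    r$t_lof_type <- "none"
    r$t_lof_confidence <- "not_lof"
    r$t_attributes <- NA_character_
    r$t_klass <- NA_character_
    r$t_tier <- NA_character_
    r$t_band <- NA_character_
    r$t_unique <- FALSE
    r$t_carriers <- NA_integer_
    r
  }

  set_insilico <- function(r, profile) {
    if (profile == "deleterious") {
      r$sift_call <- "D"
      r$polyphen_call <- "D"
      r$cadd_phred <- round(stats::runif(1, 18, 35), 2)
    } else if (profile == "benign_consensus") { # still passes the cascade via CADD
      r$sift_call <- "T"
      r$polyphen_call <- "B"
      r$cadd_phred <- round(stats::runif(1, 15.5, 18), 2)
    } else if (profile == "mixed_vus") { # SIFT+PolyPhen deleterious, CADD low
      r$sift_call <- "D"
      r$polyphen_call <- "D"
      r$cadd_phred <- round(stats::runif(1, 5, 14), 2)
    } else if (profile == "all_benign") { # fails the deleteriousness stage
      r$sift_call <- "T"
      r$polyphen_call <- "B"
      r$cadd_phred <- round(stats::runif(1, 3, 12), 2)
    } else if (profile == "cadd_only") { # LoF variants: CADD is the only tool
      r$cadd_phred <- round(stats::runif(1, 20, 35), 2)
    }
    r
  }

  set_rare_afs <- function(r, datasets = c("1000g_all", "gnomad_all", "esp6500_all")) {
    for (ds in datasets) r[[paste0("af_", ds)]] <- draw(spec$rare_af_range)
    r <- sync_gnomad_counts(r)
    r
  }

  set_common_afs <- function(r) {
    for (ds in c("1000g_all", "gnomad_all", "esp6500_all")) {
      r[[paste0("af_", ds)]] <- draw(spec$common_af_range)
    }
    sync_gnomad_counts(r)
  }

  set_pm2_tiny_af <- function(r) {
    r$af_gnomad_all <- draw(spec$pm2_af_range)
    sync_gnomad_counts(r)
  }

  sync_gnomad_counts <- function(r) {
    if (!is.na(r$af_gnomad_all)) {
      an <- spec$ref_an[["gnomad_all"]]
      ac <- max(1, round(r$af_gnomad_all * an))
      r$ac_gnomad_all <- ac
      r$an_gnomad_all <- an
      r$af_gnomad_all <- ac / an
    }
    r
  }

  add_row <- function(r) rows[[length(rows) + 1L]] <<- r

  add_curated <- function(vid, ...) {
    curated_rows[[length(curated_rows) + 1L]] <<- tibble::tibble(variant_id = vid, ...)
  }

  # ---- pLoF branch ----------------------------------------------------------
  transcripts <- list()
  plof_gene_pool <- if (spec$plant_plp) {
    c(PLOF_PATHOGENIC_GENES, PLOF_VUS_GENES)
  } else {
    PLOF_VUS_GENES
  }
  for (g in plof_gene_pool) {
    l <- locus(g)
    transcripts[[g]] <- synth_transcript(g, l$chrom, l$base)
  }
  codon_cursor <- stats::setNames(rep(10L, length(plof_gene_pool)), plof_gene_pool)
  intron_cursor <- stats::setNames(rep(1L, length(plof_gene_pool)), plof_gene_pool)
  next_codon <- function(g) {
    c0 <- codon_cursor[[g]]
    codon_cursor[[g]] <<- c0 + 5L
    c0
  }
  next_intron <- function(g) {
    i0 <- intron_cursor[[g]]
    if (i0 > 2L) stop("no free intron left on gene ", g)
    intron_cursor[[g]] <<- i0 + 1L
    i0
  }

  plof_plants <- list()
  plant_on <- function(gene, type, kind = NULL, codon = NULL, intron = NULL) {
    tx <- transcripts[[gene]]
    out <- switch(type,
      stopgain = plant_stopgain(tx, codon %||% next_codon(gene)),
      frameshift = plant_frameshift(tx, codon %||% next_codon(gene), kind = kind %||% "del"),
      splice = plant_splice(tx, intron %||% next_intron(gene))
    )
    transcripts[[gene]] <<- out$tx
    out
  }

  plof_specs <- list()
  if (spec$plant_plp) {
    t2 <- fixtures$plof
    for (i in seq_len(nrow(t2))) {
      plof_specs[[length(plof_specs) + 1L]] <- list(
        gene = t2$gene[i], fixture = as.list(t2[i, ]),
        type = switch(t2$lof_type[i],
          stopgain = "stopgain", splicing = "splice",
          frameshift_deletion = "frameshift", frameshift_insertion = "frameshift"
        ),
        kind = switch(t2$lof_type[i],
          frameshift_deletion = "del", frameshift_insertion = "dup", NULL
        ),
        role = "pathogenic"
      )
    }
  }
  n_path_splice <- sum(vapply(plof_specs, function(s) s$type == "splice", logical(1)))
  n_path_stop <- sum(vapply(plof_specs, function(s) s$type == "stopgain", logical(1)))
  n_path_frame <- sum(vapply(plof_specs, function(s) s$type == "frameshift", logical(1)))
  vus_mix <- c(
    rep("splice", spec$n_hc_splice - n_path_splice),
    rep("stopgain", spec$n_hc_stopgain - n_path_stop),
    rep("frameshift", spec$n_hc_frameshift - n_path_frame)
  )
  for (i in seq_along(vus_mix)) {
    g <- PLOF_VUS_GENES[(i - 1L) %% length(PLOF_VUS_GENES) + 1L]
    if (vus_mix[i] == "splice" && intron_cursor[[g]] > 2L) {
      g <- PLOF_VUS_GENES[which(intron_cursor[PLOF_VUS_GENES] <= 2L)[1]]
    }
    plof_specs[[length(plof_specs) + 1L]] <- list(
      gene = g, fixture = NULL, type = vus_mix[i],
      kind = if (vus_mix[i] == "frameshift") c("del", "dup")[(i %% 2L) + 1L] else NULL,
      role = "vus"
    )
  }

  n_vus_plof <- sum(vapply(plof_specs, function(s) s$role == "vus", logical(1)))
  vus_unique_idx <- seq_len(min(spec$n_plof_vus_unique, n_vus_plof))

  vus_seen <- 0L
  carrier_tab <- if (spec$plant_plp) fixtures$carriers else NULL
  for (s in plof_specs) {
    pl <- plant_on(s$gene, s$type, kind = s$kind)
    r <- blank_row()
    l <- locus(s$gene)
    r$chrom <- l$chrom
    r$pos <- pl$pos
    r$ref <- pl$ref
    r$alt <- pl$alt
    r$gene <- s$gene
    r$transcript <- transcripts[[s$gene]]$tx_id
    r$consequence <- switch(s$type,
      stopgain = "stopgain", splice = "splicing",
      frameshift = if (nchar(pl$ref) > nchar(pl$alt)) "frameshift_deletion" else "frameshift_insertion"
    )
    r$region <- if (s$type == "splice") "splicing" else "exonic"
    r$t_exonic <- r$region == "exonic"
    r$t_branch <- "plof"
    r$t_lof_type <- if (s$type == "splice") "splice_site" else s$type
    r$t_lof_confidence <- "HC"
    r <- set_insilico(r, "cadd_only")
    r$t_deleterious <- TRUE

    if (s$role == "pathogenic") {
      fx <- s$fixture
      r$hgvs_c <- fx$hgvs_c
      r$hgvs_p <- fx$hgvs_p
      r$dbsnp_id <- fx$dbsnp_id
      r$clinvar_sig <- fx$clinvar_sig
      r$t_attributes <- fx$attributes
      r$t_klass <- fx$klass
      r$t_tier <- fx$tier
      r$t_band <- "pathogenic"
      r$t_unique <- fx$unique
      if (!fx$unique && is.na(fx$dbsnp_id) && is.na(fx$clinvar_sig)) {
        r <- set_pm2_tiny_af(r) # observed somewhere, still PM2-rare
      }
      if (!is.na(fx$functional_evidence)) r$in_literature <- TRUE
      if (s$gene == "PKP2") {
        add_curated(variant_id(r$chrom, r$pos, r$ref, r$alt), segregation = TRUE)
      }
      cc <- carrier_tab[carrier_tab$gene == s$gene & carrier_tab$hgvs_c == fx$hgvs_c, ]
      r$t_carriers <- cc$n_carriers[1]
    } else {
      vus_seen <- vus_seen + 1L
      uniq <- vus_seen %in% vus_unique_idx
      r$hgvs_c <- paste0("c.", r$pos - l$base, r$ref, ">", substr(r$alt, 1, 1))
      r$t_unique <- uniq
      if (!uniq) {
        r$dbsnp_id <- next_rs()
        r$af_gnomad_all <- draw(c(2e-4, 5e-3))
        r <- sync_gnomad_counts(r)
      }
      r$t_attributes <- if (uniq) "PM2PP3" else "PP3"
      r$t_klass <- "VUS"
      r$t_band <- "other"
    }
    add_row(r)
  }

  # ---- planted low-confidence LoF ------------------------------------------
  lc_specs <- list(
    list(gene = "SCN5A", type = "stopgain", codon = 250L, reason = "last_exon"),
    list(gene = "AKAP9", type = "stopgain", codon = 260L, reason = "last_exon"),
    list(gene = "TRPM4", type = "frameshift", codon = 190L, reason = "final_junction_50bp")
  )
  for (s in utils::head(lc_specs, spec$n_lc)) {
    pl <- plant_on(s$gene, s$type, kind = "del", codon = s$codon)
    r <- blank_row()
    l <- locus(s$gene)
    r$chrom <- l$chrom
    r$pos <- pl$pos
    r$ref <- pl$ref
    r$alt <- pl$alt
    r$gene <- s$gene
    r$transcript <- transcripts[[s$gene]]$tx_id
    r$consequence <- if (s$type == "stopgain") "stopgain" else "frameshift_deletion"
    r$region <- "exonic"
    r$t_exonic <- TRUE
    r$t_branch <- "plof"
    r$t_lof_type <- if (s$type == "stopgain") "stopgain" else "frameshift"
    r$t_lof_confidence <- "LC"
    r <- set_insilico(r, "cadd_only")
    r$t_deleterious <- TRUE
    r$hgvs_c <- paste0("c.", r$pos - l$base, "lc")
    r$dbsnp_id <- next_rs()
    r$af_gnomad_all <- draw(c(2e-4, 5e-3))
    r <- sync_gnomad_counts(r)
    add_row(r)
  }

  # ---- nonsynonymous branch: published P/LP sets ----------------------------
  if (spec$plant_plp) {
    t1 <- fixtures$nonsyn
    for (i in seq_len(nrow(t1))) {
      g <- t1$gene[i]
      l <- locus(g)
      attrs <- t1$attributes[i]
      has <- function(code) grepl(code, attrs, fixed = TRUE)
      r <- blank_row()
      r$chrom <- l$chrom
      r$pos <- if (has("PM1")) next_hotspot_pos(env, g) else next_plain_pos(env, g)
      ra <- parse_snv_hgvs(t1$hgvs_c[i])
      r$ref <- ra[1]
      r$alt <- ra[2]
      r$gene <- g
      r$consequence <- "missense"
      r$region <- "exonic"
      r$hgvs_c <- t1$hgvs_c[i]
      r$hgvs_p <- t1$hgvs_p[i]
      r$dbsnp_id <- t1$dbsnp_id[i]
      r$clinvar_sig <- t1$clinvar_sig[i]
      r <- set_insilico(r, if (has("BP4")) "benign_consensus" else "deleterious")
      if (!has("PM2")) {
        r <- set_rare_afs(r)
      } else if (!t1$unique[i] && is.na(t1$dbsnp_id[i]) && is.na(t1$clinvar_sig[i])) {
        r <- set_pm2_tiny_af(r)
      }
      if (!is.na(t1$functional_evidence[i])) r$in_literature <- TRUE
      r$t_branch <- "nonsyn"
      r$t_exonic <- TRUE
      r$t_nonsyn <- TRUE
      r$t_deleterious <- TRUE
      r$t_survivor_nonsyn <- TRUE
      r$t_attributes <- attrs
      r$t_klass <- t1$klass[i]
      r$t_tier <- t1$tier[i]
      r$t_band <- confidence_band(t1$klass[i], t1$tier[i])
      r$t_unique <- t1$unique[i]
      vid <- variant_id(r$chrom, r$pos, r$ref, r$alt)
      cur <- list()
      if (has("PS3")) {
        cur$functional_effect <- "damaging"
        cur$citation <- t1$functional_evidence[i]
      }
      if (has("BS3")) {
        cur$functional_effect <- "benign_shown"
        cur$citation <- t1$functional_evidence[i]
      }
      if (has("PM5")) cur$same_residue_pathogenic <- TRUE
      if (g == "KCNQ1" && !has("BP1")) cur$remove_codes <- "BP1"
      if (length(cur) > 0) do.call(add_curated, c(list(vid), cur))
      if (r$t_band %in% c("pathogenic", "lp_high")) {
        cc <- carrier_tab[carrier_tab$gene == g & carrier_tab$hgvs_c == t1$hgvs_c[i], ]
        r$t_carriers <- cc$n_carriers[1]
      }
      add_row(r)
    }
  }

  # ---- nonsynonymous branch: VUS and likely benign --------------------------
  lof_mech_genes <- panel$gene[panel$lof_mechanism]
  constrained_genes <- panel$gene[panel$missense_constrained]
  n_hot <- round(0.582 * spec$n_vus)
  vus_genes <- c(
    rep(VUS_HOT_GENES, length.out = n_hot),
    rep(setdiff(panel$gene, VUS_HOT_GENES), length.out = spec$n_vus - n_hot)
  )
  for (i in seq_len(spec$n_vus)) {
    g <- vus_genes[i]
    l <- locus(g)
    uniq <- i <= spec$n_vus_unique
    r <- blank_row()
    r$chrom <- l$chrom
    r$pos <- next_plain_pos(env, g)
    ra <- random_snv()
    r$ref <- ra[1]
    r$alt <- ra[2]
    r$gene <- g
    r$consequence <- "missense"
    r$region <- "exonic"
    r$hgvs_c <- paste0("c.", r$pos - l$base, r$ref, ">", r$alt)
    r <- set_insilico(r, "mixed_vus")
    if (!uniq) {
      r$dbsnp_id <- next_rs()
      r <- set_rare_afs(r, datasets = "gnomad_all")
    }
    r$t_branch <- "nonsyn"
    r$t_exonic <- TRUE
    r$t_nonsyn <- TRUE
    r$t_deleterious <- TRUE
    r$t_survivor_nonsyn <- TRUE
    attrs <- c(
      if (uniq) "PM2",
      if (g %in% constrained_genes) "PP2",
      "PP3",
      if (g %in% lof_mech_genes) "BP1"
    )
    r$t_attributes <- paste(attrs, collapse = "")
    r$t_klass <- "VUS"
    r$t_band <- "other"
    r$t_unique <- uniq
    add_row(r)
  }

  lb_gene_pool <- c(
    rep("KCNH2", 6), rep("PKP2", 7),
    rep(c("SCN1B", "SNTA1", "HCN4"), length.out = max(0, spec$n_lb - 13))
  )
  lb_genes <- lb_gene_pool[seq_len(min(spec$n_lb, length(lb_gene_pool)))]
  # unique LB rows come from the BP1-capable genes (no curated entry needed)
  lb_unique_idx <- which(lb_genes %in% c("KCNH2", "PKP2"))
  lb_unique_idx <- utils::head(c(
    lb_unique_idx[lb_genes[lb_unique_idx] == "KCNH2"][1],
    lb_unique_idx[lb_genes[lb_unique_idx] == "PKP2"]
  ), spec$n_lb_unique)
  lb_unique_idx <- lb_unique_idx[!is.na(lb_unique_idx)]
  for (i in seq_along(lb_genes)) {
    g <- lb_genes[i]
    l <- locus(g)
    uniq <- i %in% lb_unique_idx
    r <- blank_row()
    r$chrom <- l$chrom
    r$pos <- next_plain_pos(env, g)
    ra <- random_snv()
    r$ref <- ra[1]
    r$alt <- ra[2]
    r$gene <- g
    r$consequence <- "missense"
    r$region <- "exonic"
    r$hgvs_c <- paste0("c.", r$pos - l$base, r$ref, ">", r$alt)
    r <- set_insilico(r, "benign_consensus")
    if (!uniq) {
      r$dbsnp_id <- next_rs()
      r <- set_rare_afs(r, datasets = "gnomad_all")
    }
    vid <- variant_id(r$chrom, r$pos, r$ref, r$alt)
    if (!(g %in% lof_mech_genes)) add_curated(vid, reputable_benign = TRUE)
    r$t_branch <- "nonsyn"
    r$t_exonic <- TRUE
    r$t_nonsyn <- TRUE
    r$t_deleterious <- TRUE
    r$t_survivor_nonsyn <- TRUE
    attrs <- c(
      if (uniq) "PM2",
      "BP4",
      if (g %in% lof_mech_genes) "BP1" else "BP6"
    )
    r$t_attributes <- paste(attrs, collapse = "")
    r$t_klass <- "Likely_benign"
    r$t_band <- "other"
    r$t_unique <- uniq
    add_row(r)
  }

  # ---- planted cascade failures --------------------------------------------
  all_genes <- panel$gene
  fail_gene <- function(i) all_genes[(i - 1L) %% length(all_genes) + 1L]
  for (i in seq_len(spec$n_common)) {
    g <- fail_gene(i)
    r <- blank_row()
    l <- locus(g)
    r$chrom <- l$chrom
    r$pos <- next_plain_pos(env, g)
    ra <- random_snv()
    r$ref <- ra[1]
    r$alt <- ra[2]
    r$gene <- g
    r$consequence <- "missense"
    r$region <- "exonic"
    r$hgvs_c <- paste0("c.", r$pos - l$base, r$ref, ">", r$alt)
    r <- set_insilico(r, "deleterious")
    r <- set_common_afs(r)
    r$dbsnp_id <- next_rs()
    r$t_rare <- FALSE
    r$t_exonic <- TRUE
    r$t_nonsyn <- TRUE
    r$t_deleterious <- TRUE
    add_row(r)
  }
  for (i in seq_len(spec$n_intronic)) {
    g <- fail_gene(i + 7L)
    r <- blank_row()
    l <- locus(g)
    r$chrom <- l$chrom
    r$pos <- next_plain_pos(env, g)
    ra <- random_snv()
    r$ref <- ra[1]
    r$alt <- ra[2]
    r$gene <- g
    r$consequence <- "intronic"
    r$region <- "intronic"
    r$hgvs_c <- paste0("c.", r$pos - l$base, "-12", r$ref, ">", r$alt)
    r <- set_rare_afs(r)
    r$dbsnp_id <- next_rs()
    add_row(r)
  }
  for (i in seq_len(spec$n_synonymous)) {
    g <- fail_gene(i + 17L)
    r <- blank_row()
    l <- locus(g)
    r$chrom <- l$chrom
    r$pos <- next_plain_pos(env, g)
    ra <- random_snv()
    r$ref <- ra[1]
    r$alt <- ra[2]
    r$gene <- g
    r$consequence <- "synonymous"
    r$region <- "exonic"
    r$hgvs_c <- paste0("c.", r$pos - l$base, r$ref, ">", r$alt)
    r <- set_rare_afs(r)
    r$dbsnp_id <- next_rs()
    r$t_exonic <- TRUE
    add_row(r)
  }
  for (i in seq_len(spec$n_benign_predicted)) {
    g <- fail_gene(i + 23L)
    r <- blank_row()
    l <- locus(g)
    r$chrom <- l$chrom
    r$pos <- next_plain_pos(env, g)
    ra <- random_snv()
    r$ref <- ra[1]
    r$alt <- ra[2]
    r$gene <- g
    r$consequence <- "missense"
    r$region <- "exonic"
    r$hgvs_c <- paste0("c.", r$pos - l$base, r$ref, ">", r$alt)
    r <- set_insilico(r, "all_benign")
    r <- set_rare_afs(r)
    r$dbsnp_id <- next_rs()
    r$t_exonic <- TRUE
    r$t_nonsyn <- TRUE
    add_row(r)
  }
  for (i in seq_len(spec$n_clinvar_benign)) {
    g <- fail_gene(i + 29L)
    r <- blank_row()
    l <- locus(g)
    r$chrom <- l$chrom
    r$pos <- next_plain_pos(env, g)
    ra <- random_snv()
    r$ref <- ra[1]
    r$alt <- ra[2]
    r$gene <- g
    r$consequence <- "missense"
    r$region <- "exonic"
    r$hgvs_c <- paste0("c.", r$pos - l$base, r$ref, ">", r$alt)
    r <- set_insilico(r, "deleterious")
    r <- set_rare_afs(r)
    r$dbsnp_id <- next_rs()
    r$clinvar_sig <- "Benign"
    r$t_exonic <- TRUE
    r$t_nonsyn <- TRUE
    r$t_deleterious <- TRUE
    r$t_not_benign <- FALSE
    add_row(r)
  }

  # ---- assemble, genotype, write -------------------------------------------
  truth <- if (length(rows)) {
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  } else {
    tibble::as_tibble(blank_row())[0, ]
  }
  if (nrow(truth) > 0) {
    gidx <- match(truth$gene, loci$gene)
    truth <- truth[order(gidx, truth$pos), , drop = FALSE]
    truth$variant_id <- variant_id(truth$chrom, truth$pos, truth$ref, truth$alt)
    # canonical code order, so truth strings compare directly to engine output
    truth$t_attributes <- vapply(truth$t_attributes, function(s) {
      if (is.na(s)) NA_character_ else format_acmg(parse_acmg(s))
    }, character(1), USE.NAMES = FALSE)
    if (anyDuplicated(truth$variant_id)) {
      stop("internal generator error: duplicated variant positions")
    }
  } else {
    truth$variant_id <- character(0)
  }

  samples <- sprintf("S%04d", seq_len(spec$n_samples))
  zyg <- matrix(0L, nrow(truth), spec$n_samples,
    dimnames = list(truth$variant_id, samples)
  )
  next_free_sample <- 1L
  for (i in seq_len(nrow(truth))) {
    if (!is.na(truth$t_carriers[i])) {
      k <- truth$t_carriers[i]
      zyg[i, next_free_sample:(next_free_sample + k - 1L)] <- 1L
      next_free_sample <- next_free_sample + k
    } else {
      af <- stats::runif(1, spec$cohort_af_range[1], spec$cohort_af_range[2])
      z <- stats::rbinom(spec$n_samples, 2L, af)
      if (sum(z) == 0) z[(i - 1L) %% spec$n_samples + 1L] <- 1L
      zyg[i, ] <- z
    }
  }
  genotypes <- cohort_genotypes(zyg, samples)

  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    annotations = file.path(dir, "annotations.tsv"),
    reference_counts = file.path(dir, "reference_counts.tsv"),
    truthbook = file.path(dir, "truthbook.json"),
    curated_variants = file.path(dir, "curated_evidence.tsv"),
    hotspots = file.path(dir, "hotspots.tsv"),
    transcripts_gff = file.path(dir, "transcripts.gff3")
  )

  write_cohort_vcf(truth, genotypes, paths$vcf)
  ann_cols <- c(
    "chrom", "pos", "ref", "alt", "gene", "transcript", "consequence",
    "hgvs_c", "hgvs_p", "dbsnp_id", "region", "sift_call", "polyphen_call",
    "cadd_phred", "clinvar_sig", "in_literature",
    paste0("af_", REF_AF_DATASETS), "ac_gnomad_all", "an_gnomad_all"
  )
  write_variant_table(truth[, ann_cols, drop = FALSE], paths$annotations)

  ref_counts <- build_reference_counts(truth, spec)
  data.table::fwrite(ref_counts, paths$reference_counts, sep = "\t", na = "NA", quote = FALSE)

  per_variant <- if (length(curated_rows)) {
    dplyr::bind_rows(curated_rows)
  } else {
    tibble::tibble(variant_id = character(0))
  }
  hotspots <- tibble::tibble(
    gene = loci$gene, start = loci$base + 800000L, end = loci$base + 801000L
  )
  curated <- curated_evidence(per_variant = per_variant, hotspots = hotspots)
  data.table::fwrite(per_variant, paths$curated_variants, sep = "\t", na = "NA", quote = FALSE)
  data.table::fwrite(hotspots, paths$hotspots, sep = "\t", na = "NA", quote = FALSE)

  jsonlite::write_json(truth, paths$truthbook, auto_unbox = FALSE, digits = NA, na = "null")
  write_transcript_gff3(transcripts, paths$transcripts_gff)

  c(paths, list(
    truth = truth, transcripts = transcripts, curated = curated,
    genotypes = genotypes, panel = panel, spec = spec, dir = dir
  ))
}

# Reference allele counts for the AF-comparison stage: one row per
# (high-band variant, dataset) where the dataset observed the variant;
# gnomAD-style datasets carry counts, the ESP-style dataset frequency only.
build_reference_counts <- function(truth, spec) {
  out <- list()
  band <- truth$t_band %in% c("pathogenic", "lp_high")
  for (i in which(band)) {
    for (ds in REF_AF_DATASETS) {
      af <- truth[[paste0("af_", ds)]][i]
      if (is.na(af)) next
      if (ds == "esp6500_all") {
        out[[length(out) + 1L]] <- tibble::tibble(
          variant_id = truth$variant_id[i], dataset = ds,
          ac = NA_real_, an = NA_real_, af = af
        )
      } else {
        an <- spec$ref_an[[ds]]
        ac <- max(1, round(af * an))
        out[[length(out) + 1L]] <- tibble::tibble(
          variant_id = truth$variant_id[i], dataset = ds,
          ac = ac, an = an, af = ac / an
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      variant_id = character(0), dataset = character(0),
      ac = numeric(0), an = numeric(0), af = numeric(0)
    ))
  }
  dplyr::bind_rows(out)
}

# Minimal multi-sample VCF v4.2 emitter (GT only). vcfR reads these back.
write_cohort_vcf <- function(truth, genotypes, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=channelscan_synthetic_cohort",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", genotypes$samples
    ), collapse = "\t")
  )
  if (nrow(truth) == 0) {
    writeLines(header, path, useBytes = TRUE)
    return(invisible(path))
  }
  gt_str <- matrix(c("0/0", "0/1", "1/1")[genotypes$zygosity + 1L],
    nrow = nrow(truth)
  )
  fixed <- cbind(
    truth$chrom, as.character(truth$pos),
    ifelse(is.na(truth$dbsnp_id), ".", truth$dbsnp_id),
    truth$ref, truth$alt, ".", "PASS", ".", "GT"
  )
  lines <- do.call(paste, c(
    lapply(seq_len(ncol(fixed)), function(j) fixed[, j]),
    lapply(seq_len(ncol(gt_str)), function(j) gt_str[, j]),
    sep = "\t"
  ))
  writeLines(c(header, lines), path, useBytes = TRUE)
  invisible(path)
}

# GFF3 writer for the synthetic transcript models (sequence not included).
write_transcript_gff3 <- function(transcripts, path) {
  lines <- "##gff-version 3"
  for (tx in transcripts) {
    span <- tx_span(tx)
    attr_tx <- sprintf(
      "ID=%s;gene_id=%s;canonical=%s", tx$tx_id, tx$gene,
      if (tx$canonical) "true" else "false"
    )
    lines <- c(lines, paste(
      tx$chrom, "channelscan", "mRNA", span[1], span[2], ".", tx$strand, ".",
      attr_tx,
      sep = "\t"
    ))
    for (i in seq_along(tx$exon_starts)) {
      for (type in c("exon", "CDS")) {
        s <- max(tx$exon_starts[i], if (type == "CDS") tx$cds_start else -Inf)
        e <- min(tx$exon_ends[i], if (type == "CDS") tx$cds_end else Inf)
        if (s > e) next
        lines <- c(lines, paste(
          tx$chrom, "channelscan", type, s, e, ".", tx$strand,
          if (type == "CDS") "0" else ".",
          sprintf("Parent=%s;transcript_id=%s;gene_id=%s", tx$tx_id, tx$tx_id, tx$gene),
          sep = "\t"
        ))
      }
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
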