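# Data model for annotated cohort variants and readers/writers for the
# formats the pipeline touches: a multi-sample VCF with GT, a tab-separated
# annotation table keyed by (chrom, pos, ref, alt), and the gene-panel
# configuration. Coordinates are 1-based and fully closed throughout (VCF
# convention); inputs are assumed normalized, no left-alignment is done.

CORE_VARIANT_COLS <- c(
  "chrom", "pos", "ref", "alt", "gene", "transcript", "consequence",
  "hgvs_c", "hgvs_p", "dbsnp_id", "region", "sift_call", "polyphen_call",
  "cadd_phred", "clinvar_sig", "in_literature"
)

#' Stable variant key
#'
#' Builds the `chrom:pos:ref:alt` key used to join VCF records to annotation
#' rows, genotype matrices and truth books.
#'
#' @param chrom,pos,ref,alt vectors of equal length.
#' @return character vector of keys.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Validate an annotated variant table
#'
#' Checks the structural invariants of the variant data model: positions are
#' positive, `ref != alt`, every allele frequency lies in `[0, 1]`, and where
#' both `ac_<dataset>` and `an_<dataset>` are present, `af = ac / an` to
#' within 1e-9. Missing annotation values are `NA`, never sentinel numbers,
#' so filters can distinguish "unknown" from "0".
#'
#' @param variants a data frame with at least `chrom`, `pos`, `ref`, `alt`;
#'   annotation fields as in `CORE_VARIANT_COLS`; per-dataset frequencies in
#'   `af_<dataset>` columns (optional `ac_<dataset>` / `an_<dataset>`).
#' @return the validated table, invisibly as a tibble.
#' @export
validate_variants <- function(variants) {
  variants <- tibble::as_tibble(variants)
  need <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss) > 0) {
    stop("variant table lacks required column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(variants) > 0) {
    if (any(variants$pos < 1)) stop("variant positions must be >= 1")
    if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
    for (col in grep("^af_", names(variants), value = TRUE)) {
      v <- variants[[col]]
      if (any(v < 0 | v > 1, na.rm = TRUE)) {
        stop("allele frequencies in ", col, " outside [0, 1]")
      }
      ds <- sub("^af_", "", col)
      ac <- variants[[paste0("ac_", ds)]]
      an <- variants[[paste0("an_", ds)]]
      if (!is.null(ac) && !is.null(an)) {
        ok <- is.na(ac) | is.na(an) | is.na(v) | abs(v - ac / an) <= 1e-9
        if (!all(ok)) stop("af != ac/an for dataset ", ds)
      }
    }
  }
  invisible(variants)
}

#' Cohort genotype matrix
#'
#' Per-(variant, sample) zygosity: 0 = homozygous reference (or allele
#' absent), 1 = heterozygous, 2 = homozygous alternate. Row names are
#' [variant_id()] keys. For autosomal sites the cohort allele number is
#' `2 * length(samples)` and the cohort allele count of a variant is the
#' row sum of its zygosities.
#'
#' @param zygosity integer matrix (variants x samples) with values in 0:2;
#'   row names are variant keys.
#' @param samples character vector of sample ids (defaults to column names).
#' @return an object of class `cohort_genotypes`.
#' @export
cohort_genotypes <- function(zygosity, samples = colnames(zygosity)) {
  zygosity <- as.matrix(zygosity)
  if (is.null(samples)) samples <- sprintf("S%d", seq_len(ncol(zygosity)))
  stopifnot(length(samples) == ncol(zygosity))
  if (nrow(zygosity) > 0 && !all(zygosity %in% 0:2)) {
    stop("zygosity values must be 0, 1 or 2")
  }
  colnames(zygosity) <- samples
  structure(
    list(samples = samples, zygosity = zygosity),
    class = "cohort_genotypes"
  )
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(
    "<cohort_genotypes> ", nrow(x$zygosity), " variants x ",
    length(x$samples), " samples\n",
    sep = ""
  )
  invisible(x)
}

#' Cohort allele counts
#'
#' @param genotypes a [cohort_genotypes()] object.
#' @return named integer vector of per-variant alternate allele counts.
#' @export
cohort_ac <- function(genotypes) {
  rowSums(genotypes$zygosity)
}

#' Cohort allele number (autosomal)
#'
#' @param genotypes a [cohort_genotypes()] object.
#' @return `2 * n_samples`.
#' @export
cohort_an <- function(genotypes) {
  2L * length(genotypes$samples)
}

# Zygosity of one decomposed ALT in a vector of GT strings ("0/1", "1|1",
# "./.", ...). Counts occurrences of the 1-based alt index among the two
# called alleles; missing calls count as 0.
gt_zygosity <- function(gt, alt_index) {
  gt[is.na(gt)] <- "./."
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) sum(a == as.character(alt_index)), integer(1))
}

#' Read a cohort VCF and its annotation table
#'
#' Reads a VCF v4.x with per-sample GT, decomposes multiallelic records into
#' one row per ALT allele, and left-joins the tab-separated annotation table
#' on the `(chrom, pos, ref, alt)` key. Records without a matching
#' annotation row are retained with `NA` annotations and a warning; the join
#' is key-exact, so the order of annotation rows never changes the result.
#'
#' @param vcf_path path to a VCF (plain or bgzipped).
#' @param annotation_path path to a tab-separated annotation table whose key
#'   columns are `chrom`, `pos`, `ref`, `alt`.
#' @return a list with `variants` (tibble, one row per biallelic ALT) and
#'   `genotypes` (a [cohort_genotypes()] matrix aligned to `variants`).
#' @export
read_cohort <- function(vcf_path, annotation_path) {
  if (!file.exists(vcf_path)) stop("no such VCF: '", vcf_path, "'")
  first <- readLines(vcf_path, n = 1L, warn = FALSE)
  if (length(first) == 0 || !startsWith(first, "##fileformat=VCF")) {
    stop("malformed VCF '", vcf_path, "': line 1 is not a ##fileformat=VCF header",
      call. = FALSE
    )
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE, checkFile = FALSE),
    error = function(e) {
      stop("malformed VCF '", vcf_path, "': ", conditionMessage(e), call. = FALSE)
    }
  )
  ann <- read_variant_table(annotation_path)

  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    empty <- ann[0, , drop = FALSE]
    return(list(
      variants = tibble::as_tibble(empty),
      genotypes = cohort_genotypes(matrix(integer(0), 0, 0, dimnames = list(NULL, NULL)))
    ))
  }
  pos <- as.integer(fix$POS)
  if (any(is.na(pos))) {
    stop("malformed VCF '", vcf_path, "': non-numeric POS at record ",
      which(is.na(pos))[1],
      call. = FALSE
    )
  }
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  rec <- rep.int(seq_len(n_rec), n_alt)
  alt_idx <- unlist(lapply(n_alt, seq_len), use.names = FALSE)

  core <- tibble::tibble(
    chrom = fix$CHROM[rec],
    pos = pos[rec],
    ref = fix$REF[rec],
    alt = unlist(alts, use.names = FALSE)
  )
  key <- variant_id(core$chrom, core$pos, core$ref, core$alt)

  gt_mat <- NULL
  if (!is.null(vcf@gt) && ncol(vcf@gt) > 1) {
    raw_gt <- vcfR::extract.gt(vcf, element = "GT")
    samples <- colnames(raw_gt)
    zyg <- matrix(0L, nrow(core), length(samples),
      dimnames = list(key, samples)
    )
    for (i in seq_len(nrow(core))) {
      zyg[i, ] <- gt_zygosity(raw_gt[rec[i], ], alt_idx[i])
    }
    gt_mat <- cohort_genotypes(zyg, samples)
  } else {
    gt_mat <- cohort_genotypes(matrix(integer(0), nrow(core), 0, dimnames = list(key, NULL)))
  }

  ann_key <- variant_id(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(ann_key)) {
    stop("duplicated (chrom, pos, ref, alt) keys in annotation table")
  }
  idx <- match(key, ann_key)
  if (anyNA(idx)) {
    warning(
      sum(is.na(idx)), " VCF record(s) without an annotation row; ",
      "retained with missing annotations"
    )
  }
  extra_cols <- setdiff(names(ann), c("chrom", "pos", "ref", "alt"))
  joined <- ann[idx, extra_cols, drop = FALSE]
  variants <- validate_variants(dplyr::bind_cols(core, joined))
  list(variants = variants, genotypes = gt_mat)
}

#' Write a variant table
#'
#' Tab-separated, UTF-8, LF line endings, one row per variant in a stable
#' column order; `NA` encodes absent values so the file round-trips through
#' [read_variant_table()] losslessly.
#'
#' @param variants annotated variant tibble.
#' @param out output path.
#' @return `out`, invisibly.
#' @export
write_variant_table <- function(variants, out) {
  variants <- tibble::as_tibble(variants)
  lead <- intersect(
    c(c("chrom", "pos", "ref", "alt"), CORE_VARIANT_COLS),
    names(variants)
  )
  ordered <- variants[, c(lead, sort(setdiff(names(variants), lead))), drop = FALSE]
  ok <- tryCatch(
    {
      data.table::fwrite(ordered, out,
        sep = "\t", quote = FALSE, na = "NA",
        eol = "\n", scipen = 50
      )
      TRUE
    },
    error = function(e) FALSE, warning = function(w) FALSE
  )
  if (!ok) stop("cannot write variant table to '", out, "'")
  invisible(out)
}

#' Read a variant table written by [write_variant_table()]
#'
#' @param path path to the tab-separated table.
#' @return tibble of variants.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("no such annotation table: '", path, "'")
  dt <- data.table::fread(path,
    sep = "\t", na.strings = "NA", header = TRUE,
    colClasses = list(character = "chrom"), data.table = FALSE
  )
  tb <- tibble::as_tibble(dt)
  # all-NA columns come back from fread as logical; restore declared types
  for (col in intersect(
    c("ref", "alt", "gene", "transcript", "consequence", "hgvs_c", "hgvs_p",
      "dbsnp_id", "region", "sift_call", "polyphen_call", "clinvar_sig"),
    names(tb)
  )) {
    tb[[col]] <- as.character(tb[[col]])
  }
  for (col in c("cadd_phred", grep("^(af|ac|an)_", names(tb), value = TRUE))) {
    if (col %in% names(tb)) tb[[col]] <- as.numeric(tb[[col]])
  }
  if ("in_literature" %in% names(tb)) {
    tb$in_literature <- as.logical(tb$in_literature)
  }
  if ("pos" %in% names(tb)) tb$pos <- as.integer(tb$pos)
  tb
}

#' Load a gene-panel configuration
#'
#' The panel lists one row per gene with its evidence category (`definitive`,
#' `limited_disputed`, `acquired_only`), inheritance mode (`AD`, `AR`,
#' `both`), whether loss of function is an established disease mechanism
#' (drives PVS1/BP1), and whether the gene is missense-constrained (drives
#' PP2). The shipped default panel has 36 genes, 12 of them definitive.
#'
#' @param path panel file (tab-separated; `#` comment lines allowed).
#'   Defaults to the panel shipped with the package.
#' @return tibble of panel entries.
#' @export
load_gene_panel <- function(path = default_panel_path()) {
  panel <- read_tsv_commented(path)
  need <- c("gene", "evidence_category", "inheritance", "lof_mechanism", "missense_constrained")
  miss <- setdiff(need, names(panel))
  if (length(miss) > 0) stop("gene panel lacks column(s): ", paste(miss, collapse = ", "))
  bad_cat <- setdiff(panel$evidence_category, c("definitive", "limited_disputed", "acquired_only"))
  if (length(bad_cat) > 0) {
    stop("unknown evidence_category value(s): ", paste(bad_cat, collapse = ", "))
  }
  bad_inh <- setdiff(panel$inheritance, c("AD", "AR", "both"))
  if (length(bad_inh) > 0) {
    stop("unknown inheritance value(s): ", paste(bad_inh, collapse = ", "))
  }
  dup <- panel$gene[duplicated(panel$gene)]
  if (length(dup) > 0) {
    stop("duplicated gene symbol(s) in panel: ", paste(unique(dup), collapse = ", "))
  }
  panel$lof_mechanism <- as.logical(panel$lof_mechanism)
  panel$missense_constrained <- as.logical(panel$missense_constrained)
  panel
}

# TSV reader that strips leading '#' comment lines (fixture convention).
read_tsv_commented <- function(path, ...) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  tibble::as_tibble(data.table::fread(
    text = paste(lines, collapse = "\n"),
    sep = "\t", header = TRUE, na.strings = "NA", data.table = FALSE, ...
  ))
}

default_panel_path <- function() {
  system.file("extdata", "gene_panel.tsv", package = "channelscan", mustWork = TRUE)
}

#' Default 36-gene channelopathy panel
#'
#' @return tibble, see [load_gene_panel()].
#' @export
default_gene_panel <- function() {
  load_gene_panel(default_panel_path())
}
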