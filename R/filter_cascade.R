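# The nonsynonymous filtering cascade: rare -> exonic -> nonsynonymous ->
# predicted-deleterious -> not-ClinVar-benign, with per-stage funnel
# bookkeeping. Every stage is a pure subset operation on the variant table,
# so stages are idempotent and the cascade is monotone.

#' Filtering configuration
#'
#' @param maf_threshold minor-allele-frequency cut-off; variants with folded
#'   MAF `min(af, 1 - af) < maf_threshold` in every reference dataset where
#'   they are observed are kept (strict inequality). Default 0.05.
#' @param reference_datasets dataset names (matching `af_<name>` columns)
#'   consulted by the rarity filter.
#' @param cadd_cutoff CADD phred score above which (strictly) a variant
#'   counts as predicted deleterious. Default 15.
#' @param sift_deleterious SIFT calls counting as deleterious.
#' @param polyphen_deleterious PolyPhen calls counting as deleterious
#'   (damaging or possibly damaging).
#' @param clinvar_benign_terms ClinVar significance strings treated as benign
#'   and removed by the final stage.
#' @return a `filter_config` list.
#' @export
filter_config <- function(maf_threshold = 0.05,
                          reference_datasets = c("1000g_all", "gnomad_all", "esp6500_all"),
                          cadd_cutoff = 15,
                          sift_deleterious = "D",
                          polyphen_deleterious = c("D", "P"),
                          clinvar_benign_terms = c(
                            "Benign", "Likely_benign", "Benign/Likely_benign"
                          )) {
  stopifnot(maf_threshold > 0, maf_threshold <= 0.5, cadd_cutoff > 0)
  structure(
    list(
      maf_threshold = maf_threshold,
      reference_datasets = reference_datasets,
      cadd_cutoff = cadd_cutoff,
      sift_deleterious = sift_deleterious,
      polyphen_deleterious = polyphen_deleterious,
      clinvar_benign_terms = clinvar_benign_terms
    ),
    class = "filter_config"
  )
}

af_columns <- function(variants, datasets, where = "rarity filter") {
  cols <- paste0("af_", datasets)
  miss <- setdiff(cols, names(variants))
  if (length(miss) > 0) {
    stop(
      "unknown reference dataset(s) in ", where, ": ",
      paste(sub("^af_", "", miss), collapse = ", ")
    )
  }
  cols
}

#' Keep rare variants
#'
#' A variant passes if, in every configured reference dataset where an
#' allele frequency is recorded, the folded minor allele frequency
#' `min(af, 1 - af)` is strictly below the threshold. A variant absent from
#' all reference datasets is kept: unobserved variants are the rarest.
#'
#' @param variants annotated variant tibble.
#' @param config a [filter_config()].
#' @return the surviving subset.
#' @export
filter_rare <- function(variants, config = filter_config()) {
  if (nrow(variants) == 0) return(variants)
  cols <- af_columns(variants, config$reference_datasets)
  af <- as.matrix(variants[, cols, drop = FALSE])
  folded <- pmin(af, 1 - af)
  common_hits <- rowSums(folded >= config$maf_threshold, na.rm = TRUE)
  variants[common_hits == 0, , drop = FALSE]
}

#' Keep exonic variants
#'
#' Splicing variants are deliberately excluded here; they are handled by the
#' loss-of-function branch.
#'
#' @inheritParams filter_rare
#' @return the surviving subset.
#' @export
filter_exonic <- function(variants) {
  variants[!is.na(variants$region) & variants$region == "exonic", , drop = FALSE]
}

#' Keep nonsynonymous single-nucleotide variants
#'
#' Missense SNVs only. Stopgains, frameshifts and splice variants are
#' excluded from this branch and picked up by the pLoF branch.
#'
#' @inheritParams filter_rare
#' @return the surviving subset.
#' @export
filter_nonsynonymous <- function(variants) {
  keep <- !is.na(variants$consequence) & variants$consequence == "missense" &
    nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
  variants[keep, , drop = FALSE]
}

#' Keep predicted-deleterious variants
#'
#' One affirmative tool suffices: SIFT deleterious, PolyPhen damaging or
#' possibly damaging, or CADD strictly above the cut-off. Absent predictions
#' contribute no pass, so a variant with no predictions at all is dropped.
#'
#' @inheritParams filter_rare
#' @return the surviving subset.
#' @export
filter_deleterious <- function(variants, config = filter_config()) {
  keep <- (variants$sift_call %in% config$sift_deleterious) |
    (variants$polyphen_call %in% config$polyphen_deleterious) |
    (!is.na(variants$cadd_phred) & variants$cadd_phred > config$cadd_cutoff)
  variants[keep, , drop = FALSE]
}

#' Drop ClinVar-benign variants
#'
#' Only variants whose ClinVar significance is one of the configured benign
#' terms are removed; absent, uncertain, conflicting and pathogenic entries
#' are all retained.
#'
#' @inheritParams filter_rare
#' @return the surviving subset.
#' @export
filter_not_clinvar_benign <- function(variants, config = filter_config()) {
  variants[!(variants$clinvar_sig %in% config$clinvar_benign_terms), , drop = FALSE]
}

#' Run the full filtering cascade
#'
#' Applies rare, exonic, nonsynonymous, deleterious and not-ClinVar-benign
#' stages in order and records a funnel report: per-stage input/output
#' counts and the keys of the variants each stage dropped.
#'
#' @inheritParams filter_rare
#' @return list with `survivors` (tibble) and `funnel` (a `funnel_report`:
#'   `$stages` tibble of `stage`, `n_in`, `n_out`; `$dropped` named list of
#'   variant keys removed at each stage).
#' @export
run_cascade <- function(variants, config = filter_config()) {
  stages <- list(
    rare = function(v) filter_rare(v, config),
    exonic = filter_exonic,
    nonsynonymous = filter_nonsynonymous,
    deleterious = function(v) filter_deleterious(v, config),
    not_clinvar_benign = function(v) filter_not_clinvar_benign(v, config)
  )
  current <- variants
  rows <- vector("list", length(stages))
  dropped <- vector("list", length(stages))
  names(dropped) <- names(stages)
  for (i in seq_along(stages)) {
    n_in <- nrow(current)
    out <- stages[[i]](current)
    in_ids <- variant_id(current$chrom, current$pos, current$ref, current$alt)
    out_ids <- variant_id(out$chrom, out$pos, out$ref, out$alt)
    dropped[[i]] <- setdiff(in_ids, out_ids)
    rows[[i]] <- tibble::tibble(
      stage = names(stages)[i], n_in = n_in, n_out = nrow(out)
    )
    current <- out
  }
  funnel <- structure(
    list(stages = dplyr::bind_rows(rows), dropped = dropped),
    class = "funnel_report"
  )
  list(survivors = current, funnel = funnel)
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n")
  print(x$stages)
  invisible(x)
}

#' Serialize a funnel report as JSON
#'
#' @param funnel a `funnel_report` from [run_cascade()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_funnel_json <- function(funnel, path) {
  jsonlite::write_json(
    list(stages = funnel$stages, dropped = funnel$dropped),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
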