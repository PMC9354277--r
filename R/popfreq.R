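# Cross-population allele-frequency comparison (Fisher's exact test on
# allele-count 2x2 tables) and population-uniqueness flagging.

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Point-probability ordering: the two-sided p-value is the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table
#' (ties included within a relative tolerance).
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   `(a, b / c, d)`.
#' @param rel_tol relative tolerance for the tie comparison.
#' @return the two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b, c, d, rel_tol = 1e-7) {
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("cell counts must be non-negative")
  }
  if (any(counts != round(counts))) stop("cell counts must be integers")
  m <- a + c # column-1 margin ("successes")
  n <- b + d
  k <- a + b # row-1 margin (draws)
  if (m + n == 0 || k + c + d == 0) {
    return(1)
  }
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  min(1, sum(probs[probs <= p0 * (1 + rel_tol)]))
}

#' Dataset allele counts
#'
#' @param dataset dataset name.
#' @param ac alternate allele count (`NA` when the dataset publishes only a
#'   frequency).
#' @param an total allele number (`NA` likewise).
#' @param af allele frequency; computed from `ac / an` when counts exist.
#' @return one-row tibble.
#' @export
dataset_counts <- function(dataset, ac = NA_integer_, an = NA_integer_, af = NA_real_) {
  if (!is.na(ac) && !is.na(an)) {
    stopifnot(ac >= 0, an > 0, ac <= an)
    if (is.na(af)) af <- ac / an
  }
  tibble::tibble(dataset = dataset, ac = as.numeric(ac), an = as.numeric(an), af = af)
}

#' Compare cohort allele frequency against reference datasets
#'
#' One Fisher's exact test per reference dataset with allele counts
#' available, on the 2x2 table `(cohort ac, cohort an - ac / ref ac,
#' ref an - ac)`. References publishing only a frequency are reported
#' AF-only with no p-value.
#'
#' @param vid variant key.
#' @param cohort one-row counts tibble (see [dataset_counts()]) for the
#'   study cohort; for an autosomal variant `an` is twice the cohort size.
#' @param references tibble of reference dataset counts (rows as
#'   [dataset_counts()]).
#' @param alpha significance level for the `significant` flag.
#' @return tibble with one row per reference: `variant_id`, `dataset`,
#'   `ac`, `an`, `af`, `p_value`, `significant`.
#' @export
compare_af <- function(vid, cohort, references, alpha = 0.05) {
  stopifnot(!is.na(cohort$ac), !is.na(cohort$an))
  rows <- lapply(seq_len(nrow(references)), function(i) {
    r <- references[i, ]
    if (!is.na(r$ac) && !is.na(r$an)) {
      p <- fisher_exact_two_sided(
        cohort$ac, cohort$an - cohort$ac,
        r$ac, r$an - r$ac
      )
    } else {
      p <- NA_real_
    }
    tibble::tibble(
      variant_id = vid, dataset = r$dataset,
      ac = r$ac, an = r$an,
      af = if (!is.na(r$af)) r$af else if (!is.na(r$ac) && !is.na(r$an)) r$ac / r$an else NA_real_,
      p_value = p,
      significant = if (is.na(p)) NA else p < alpha
    )
  })
  dplyr::bind_rows(rows)
}

#' Flag a population-unique variant
#'
#' @param present logical vector: is the variant present in each queried
#'   resource (population datasets, variant databases, literature)?
#' @return `TRUE` iff the variant is absent from every listed resource.
#' @export
flag_unique <- function(present) {
  !any(present, na.rm = TRUE)
}

#' Flag population-unique variants in a table
#'
#' A variant is unique to the study cohort when it has no recorded allele
#' frequency in any reference dataset (`af_*` columns), no dbSNP id, no
#' ClinVar entry, and is not reported in the literature.
#'
#' @param variants annotated variant tibble.
#' @param af_datasets dataset names to consult; `NULL` means every `af_*`
#'   column.
#' @param database_cols columns whose non-missing value marks database
#'   presence.
#' @param literature_col logical column marking literature reports (ignored
#'   if absent).
#' @return logical vector along rows of `variants`.
#' @export
flag_unique_variants <- function(variants, af_datasets = NULL,
                                 database_cols = c("dbsnp_id", "clinvar_sig"),
                                 literature_col = "in_literature") {
  if (nrow(variants) == 0) {
    return(logical(0))
  }
  af_cols <- if (is.null(af_datasets)) {
    grep("^af_", names(variants), value = TRUE)
  } else {
    af_columns(variants, af_datasets, where = "uniqueness filter")
  }
  present <- matrix(FALSE, nrow(variants), 0)
  for (col in af_cols) {
    present <- cbind(present, !is.na(variants[[col]]) & variants[[col]] > 0)
  }
  for (col in intersect(database_cols, names(variants))) {
    present <- cbind(present, !is.na(variants[[col]]))
  }
  if (literature_col %in% names(variants)) {
    present <- cbind(present, !is.na(variants[[literature_col]]) & variants[[literature_col]])
  }
  !apply(present, 1, any)
}
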