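# Carrier counting over cohort genotypes and genotypic-prevalence
# estimation. Reporting conventions: the 1:N ratio rounds N to the nearest
# integer, while percentages are truncated (not rounded) to one decimal --
# the pair of conventions under which 10/1029 prints as "1:103" / "0.9%"
# and 19/1029 as "1:54" / "1.8%".

#' Truncate a percentage to one decimal
#'
#' @param x numeric percentage(s).
#' @return `x` truncated (floored) at one decimal place.
#' @export
truncate_percent <- function(x) {
  floor(x * 10 + 1e-9) / 10
}

#' Count carriers of classified variants
#'
#' A carrier is a sample with zygosity >= 1 for at least one variant in the
#' selected confidence bands; distinct individuals are counted once however
#' many qualifying variants they carry. Heterozygotes in autosomal-recessive
#' genes are flagged (`ar_het`) as carriers-not-affected but remain in the
#' genotypic count.
#'
#' @param classified tibble with `variant_id`, `gene` and `band` (see
#'   [confidence_band()]).
#' @param genotypes a [cohort_genotypes()] matrix covering the classified
#'   variants.
#' @param panel gene panel tibble (inheritance and evidence category).
#' @param bands which bands enter the carrier set.
#' @return object of class `carrier_summary`: `per_variant` tibble
#'   (`variant_id`, `gene`, `evidence_category`, `inheritance`,
#'   `n_carriers`, `n_hom`, `ar_het`, `carriers` list-column),
#'   `distinct_carriers`, `distinct_definitive`, `n_cohort`, `bands`.
#' @export
count_carriers <- function(classified, genotypes,
                           panel = default_gene_panel(),
                           bands = c("pathogenic", "lp_high")) {
  sel <- classified[classified$band %in% bands, , drop = FALSE]
  missing <- setdiff(sel$variant_id, rownames(genotypes$zygosity))
  if (length(missing) > 0) {
    stop(
      "variant(s) absent from genotype matrix: ",
      paste(utils::head(missing, 5), collapse = ", ")
    )
  }
  per <- vector("list", nrow(sel))
  all_carriers <- character(0)
  def_carriers <- character(0)
  for (i in seq_len(nrow(sel))) {
    z <- genotypes$zygosity[sel$variant_id[i], ]
    carriers <- genotypes$samples[z >= 1]
    entry <- panel[panel$gene == sel$gene[i], , drop = FALSE]
    inh <- if (nrow(entry) > 0) entry$inheritance[1] else NA_character_
    cat_ <- if (nrow(entry) > 0) entry$evidence_category[1] else NA_character_
    per[[i]] <- tibble::tibble(
      variant_id = sel$variant_id[i],
      gene = sel$gene[i],
      evidence_category = cat_,
      inheritance = inh,
      n_carriers = length(carriers),
      n_hom = sum(z == 2),
      ar_het = identical(inh, "AR") && any(z == 1),
      carriers = list(carriers)
    )
    all_carriers <- union(all_carriers, carriers)
    if (identical(cat_, "definitive")) def_carriers <- union(def_carriers, carriers)
  }
  structure(
    list(
      per_variant = if (length(per)) dplyr::bind_rows(per) else tibble::tibble(),
      distinct_carriers = length(all_carriers),
      distinct_definitive = length(def_carriers),
      n_cohort = length(genotypes$samples),
      bands = bands
    ),
    class = "carrier_summary"
  )
}

#' @export
print.carrier_summary <- function(x, ...) {
  cat(
    "<carrier_summary> bands {", paste(x$bands, collapse = ", "), "}: ",
    nrow(x$per_variant), " variants, ",
    x$distinct_carriers, "/", x$n_cohort, " distinct carriers (",
    x$distinct_definitive, " in definitive-evidence genes)\n",
    sep = ""
  )
  invisible(x)
}

#' Estimate genotypic prevalence
#'
#' Genotypic prevalence is the fraction of the cohort carrying at least one
#' qualifying genotype, irrespective of phenotype. Rendered both as a
#' ratio `"1:N"` with `N = round(cohort / carriers)` and as a percentage
#' truncated to one decimal.
#'
#' @param summary a `carrier_summary` from [count_carriers()], or a list
#'   with `distinct_carriers`, `distinct_definitive`, `n_cohort`.
#' @param restrict `"all"` (every panel gene) or `"definitive_only"`
#'   (carriers of variants in definitive-evidence genes).
#' @return object of class `prevalence_estimate`: `numerator`,
#'   `denominator`, `ratio_text`, `percent_text`, `percent_value` (the
#'   truncated percent as a number), or a `none_observed` marker when there
#'   are no carriers.
#' @export
estimate_prevalence <- function(summary, restrict = c("all", "definitive_only")) {
  restrict <- match.arg(restrict)
  num <- if (restrict == "definitive_only") {
    summary$distinct_definitive
  } else {
    summary$distinct_carriers
  }
  den <- summary$n_cohort
  if (num == 0) {
    return(structure(
      list(
        none_observed = TRUE, numerator = 0L, denominator = den,
        ratio_text = NA_character_, percent_text = NA_character_,
        percent_value = NA_real_, restrict = restrict
      ),
      class = "prevalence_estimate"
    ))
  }
  stopifnot(num <= den)
  pct <- truncate_percent(100 * num / den)
  structure(
    list(
      none_observed = FALSE,
      numerator = num, denominator = den,
      ratio_text = sprintf("1:%d", round(den / num)),
      percent_text = sprintf("%.1f%%", pct),
      percent_value = pct,
      restrict = restrict
    ),
    class = "prevalence_estimate"
  )
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  if (isTRUE(x$none_observed)) {
    cat("<prevalence_estimate> none observed (0/", x$denominator, ")\n", sep = "")
  } else {
    cat(
      "<prevalence_estimate> ", x$numerator, "/", x$denominator, " = ",
      x$ratio_text, " (", x$percent_text, ")",
      if (x$restrict == "definitive_only") " [definitive genes only]", "\n",
      sep = ""
    )
  }
  invisible(x)
}
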