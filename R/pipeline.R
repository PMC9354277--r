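# End-to-end orchestration: the two Fig-style branches (nonsynonymous
# cascade; pLoF calling) run independently and merge by variant key, with
# the pLoF branch winning on conflict so a truncating variant is never
# double-counted. Downstream: attribute assignment, classification,
# uniqueness, allele-frequency comparison, carrier counting, prevalence.

#' Run the full triage pipeline
#'
#' @param vcf_path cohort VCF with per-sample GT.
#' @param annotation_path tab-separated annotation table (see
#'   [read_cohort()]).
#' @param panel gene panel tibble.
#' @param transcripts named list (by gene) of [transcript_model()]s for the
#'   pLoF branch; `NULL` disables the branch.
#' @param curated a [curated_evidence()] container.
#' @param filter_cfg a [filter_config()].
#' @param acmg_cfg an [acmg_config()].
#' @param mode classification conflict mode, see [acmg_combine()].
#' @param alpha significance level for allele-frequency comparisons.
#' @param ref_counts_path optional reference allele-count table
#'   (`variant_id`, `dataset`, `ac`, `an`, `af`) for Fisher comparisons of
#'   the pathogenic / high-confidence variants.
#' @param out_dir optional directory; when given, funnel, classification,
#'   AF-comparison and prevalence reports are written there (TSV + JSON).
#' @return object of class `channelscan_run`: list with `variants`,
#'   `genotypes`, `funnel`, `survivors_nonsyn`, `plof_calls`, `merged`
#'   (survivor table with branch, attributes, class, tier, band, unique),
#'   `af_comparisons`, `carriers`, `prevalence_all`,
#'   `prevalence_definitive`, `unique_by_class`, `summary`.
#' @export
run_pipeline <- function(vcf_path, annotation_path,
                         panel = default_gene_panel(),
                         transcripts = NULL,
                         curated = curated_evidence(),
                         filter_cfg = filter_config(),
                         acmg_cfg = acmg_config(),
                         mode = "table_faithful",
                         alpha = 0.05,
                         ref_counts_path = NULL,
                         out_dir = NULL) {
  cohort <- read_cohort(vcf_path, annotation_path)
  variants <- cohort$variants
  genotypes <- cohort$genotypes
  ids <- if (nrow(variants)) {
    variant_id(variants$chrom, variants$pos, variants$ref, variants$alt)
  } else {
    character(0)
  }

  cascade <- run_cascade(variants, filter_cfg)
  nonsyn <- cascade$survivors
  nonsyn_ids <- if (nrow(nonsyn)) {
    variant_id(nonsyn$chrom, nonsyn$pos, nonsyn$ref, nonsyn$alt)
  } else {
    character(0)
  }

  plof_calls <- if (!is.null(transcripts)) {
    collect_plof(variants, panel, transcripts)
  } else {
    tibble::tibble(
      variant_id = character(0), gene = character(0),
      lof_type = character(0), confidence = character(0), reasons = character(0)
    )
  }

  # merge: nonsynonymous survivors plus HC pLoF, pLoF branch wins on overlap
  merged_ids <- union(nonsyn_ids, plof_calls$variant_id)
  merged <- variants[match(merged_ids, ids), , drop = FALSE]
  branch <- ifelse(merged_ids %in% plof_calls$variant_id, "plof", "nonsyn")

  evidence <- assign_attributes_batch(
    merged,
    lof_calls = plof_calls, panel = panel,
    curated = curated, config = acmg_cfg
  )
  classes <- classify_batch(evidence$attributes, mode = mode)
  merged_out <- dplyr::bind_cols(
    tibble::tibble(variant_id = merged_ids, branch = branch),
    merged,
    evidence["attributes"], classes[, c("klass", "tier", "band")]
  )
  merged_out$unique <- flag_unique_variants(merged)

  high <- merged_out[merged_out$band %in% c("pathogenic", "lp_high"), , drop = FALSE]

  af_comparisons <- tibble::tibble()
  if (!is.null(ref_counts_path) && nrow(high) > 0 && length(genotypes$samples) > 0) {
    refs <- tibble::as_tibble(data.table::fread(ref_counts_path,
      sep = "\t",
      na.strings = "NA", data.table = FALSE
    ))
    an <- cohort_an(genotypes)
    acs <- cohort_ac(genotypes)
    cmp <- lapply(high$variant_id, function(vid) {
      r <- refs[refs$variant_id == vid, , drop = FALSE]
      if (nrow(r) == 0) {
        return(NULL)
      }
      compare_af(
        vid,
        dataset_counts("cohort", ac = acs[[vid]], an = an),
        r[, c("dataset", "ac", "an", "af")],
        alpha = alpha
      )
    })
    af_comparisons <- dplyr::bind_rows(cmp)
  }

  carriers <- NULL
  prevalence_all <- prevalence_definitive <- NULL
  if (length(genotypes$samples) > 0) {
    carriers <- count_carriers(
      merged_out[, c("variant_id", "gene", "band")], genotypes, panel
    )
    prevalence_all <- estimate_prevalence(carriers, "all")
    prevalence_definitive <- estimate_prevalence(carriers, "definitive_only")
  }

  unique_by_class <- report_unique_by_class(merged_out, merged_out$unique)

  summary <- list(
    n_input_records = nrow(variants),
    n_nonsyn_survivors = length(nonsyn_ids),
    n_hc_plof = nrow(plof_calls),
    n_merged_survivors = nrow(merged_out),
    n_plp_band = nrow(high),
    n_unique = sum(merged_out$unique),
    n_carriers = if (is.null(carriers)) NA_integer_ else carriers$distinct_carriers,
    n_carriers_definitive = if (is.null(carriers)) NA_integer_ else carriers$distinct_definitive,
    prevalence_all = if (is.null(prevalence_all)) NULL else prevalence_all[c("ratio_text", "percent_text")],
    prevalence_definitive = if (is.null(prevalence_definitive)) NULL else prevalence_definitive[c("ratio_text", "percent_text")]
  )

  run <- structure(
    list(
      variants = variants, genotypes = genotypes,
      funnel = cascade$funnel, survivors_nonsyn = nonsyn,
      plof_calls = plof_calls, merged = merged_out,
      af_comparisons = af_comparisons, carriers = carriers,
      prevalence_all = prevalence_all,
      prevalence_definitive = prevalence_definitive,
      unique_by_class = unique_by_class,
      summary = summary
    ),
    class = "channelscan_run"
  )
  if (!is.null(out_dir)) write_run_reports(run, out_dir)
  run
}

#' @export
print.channelscan_run <- function(x, ...) {
  s <- x$summary
  cat("<channelscan_run>\n")
  cat("  input records:        ", s$n_input_records, "\n")
  cat("  nonsyn survivors:     ", s$n_nonsyn_survivors, "\n")
  cat("  HC pLoF:              ", s$n_hc_plof, "\n")
  cat("  merged survivors:     ", s$n_merged_survivors, "\n")
  cat("  P / LP-high variants: ", s$n_plp_band, "\n")
  cat("  population-unique:    ", s$n_unique, "\n")
  if (!is.na(s$n_carriers)) {
    cat("  distinct carriers:    ", s$n_carriers, " (", s$n_carriers_definitive,
      " in definitive genes)\n",
      sep = ""
    )
    cat(
      "  genotypic prevalence: ", s$prevalence_all$ratio_text, " (",
      s$prevalence_all$percent_text, "); definitive genes ",
      s$prevalence_definitive$ratio_text, " (",
      s$prevalence_definitive$percent_text, ")\n",
      sep = ""
    )
  }
  invisible(x)
}

#' Cross-tabulate uniqueness by classification band
#'
#' Percentages are among the unique variants, truncated to one decimal (so
#' they sum to at most 100.0).
#'
#' @param classified tibble with at least `klass` and `band`.
#' @param unique_flags logical vector along `classified`.
#' @return tibble with `category`, `n`, `percent` for the unique variants;
#'   zero rows when nothing is unique.
#' @export
report_unique_by_class <- function(classified, unique_flags) {
  u <- classified[unique_flags, , drop = FALSE]
  if (nrow(u) == 0) {
    return(tibble::tibble(
      category = character(0), n = integer(0), percent = numeric(0)
    ))
  }
  category <- ifelse(
    u$klass %in% c("Pathogenic", "Likely_pathogenic"),
    ifelse(u$band == "pathogenic", "pathogenic",
      ifelse(u$band == "lp_high", "lp_high", "lp_low")
    ),
    u$klass
  )
  tab <- table(category)
  tibble::tibble(
    category = names(tab),
    n = as.integer(tab),
    percent = truncate_percent(100 * as.integer(tab) / nrow(u))
  )
}

#' Write the pipeline reports
#'
#' @param run a `channelscan_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_funnel_json(run$funnel, file.path(out_dir, "funnel.json"))
  data.table::fwrite(run$merged, file.path(out_dir, "classifications.tsv"),
    sep = "\t", na = "NA", quote = FALSE
  )
  if (nrow(run$af_comparisons) > 0) {
    data.table::fwrite(run$af_comparisons, file.path(out_dir, "af_comparisons.tsv"),
      sep = "\t", na = "NA", quote = FALSE
    )
  }
  data.table::fwrite(run$unique_by_class, file.path(out_dir, "unique_by_class.tsv"),
    sep = "\t", na = "NA", quote = FALSE
  )
  jsonlite::write_json(
    run$summary,
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(out_dir)
}
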