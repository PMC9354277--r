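# ACMG/AMP evidence handling: parsing concatenated attribute strings
# ("PS3PM2PP2BP4"), rule-driven attribute assignment from annotations and
# curated evidence, and the combination engine that turns an evidence set
# into a five-class call with a Pathogenic / Likely-Pathogenic subclass
# tier. Tier evaluation order within the PVS1 branch is Ia, Ib, Id, Ic:
# with two or more supporting codes alongside PVS1 the call is Id even when
# a moderate code is also present, which is the only sub-rule ordering
# consistent with published tier assignments (PVS1+PM2+PP3 -> Ic but
# PVS1+PM2+PP3+PP5 -> Id).

ACMG_CODES <- c(
  "PVS1",
  paste0("PS", 1:4),
  paste0("PM", 1:6),
  paste0("PP", 1:5),
  "BA1",
  paste0("BS", 1:4),
  paste0("BP", 1:7)
)

#' Parse a concatenated ACMG/AMP attribute string
#'
#' Splits strings like `"PS3PM2PP2BP4"` on the code grammar (2-3 letters
#' followed by a digit) and validates every token against the controlled
#' vocabulary. Duplicate codes are collapsed (an evidence set has no
#' duplicates).
#'
#' @param x a single attribute string, or a character vector of codes.
#' @return character vector of codes.
#' @export
parse_acmg <- function(x) {
  if (length(x) == 0 || (length(x) == 1 && (is.na(x) || x == ""))) {
    return(character(0))
  }
  if (length(x) > 1 || x %in% ACMG_CODES) {
    codes <- as.character(x)
  } else {
    m <- gregexpr("(PVS|PS|PM|PP|BA|BS|BP)[0-9]", x)[[1]]
    codes <- regmatches(x, gregexpr("(PVS|PS|PM|PP|BA|BS|BP)[0-9]", x))[[1]]
    if (sum(attr(m, "match.length")) != nchar(x)) {
      stop("cannot parse ACMG attribute string: '", x, "'")
    }
  }
  bad <- setdiff(codes, ACMG_CODES)
  if (length(bad) > 0) {
    stop("unknown ACMG/AMP code(s): ", paste(bad, collapse = ", "))
  }
  unique(codes)
}

# Canonical display order for an evidence set.
format_acmg <- function(codes) {
  paste(ACMG_CODES[ACMG_CODES %in% codes], collapse = "")
}

acmg_counts <- function(codes) {
  list(
    pvs = "PVS1" %in% codes,
    ps = sum(codes %in% paste0("PS", 1:4)),
    pm = sum(codes %in% paste0("PM", 1:6)),
    pp = sum(codes %in% paste0("PP", 1:5)),
    ba = "BA1" %in% codes,
    bs = sum(codes %in% paste0("BS", 1:4)),
    bp = sum(codes %in% paste0("BP", 1:7))
  )
}

# Ordered combining sub-rules. Each rule is (class, tier, predicate).
acmg_rules <- function() {
  list(
    list("Pathogenic", "Ia", function(n) n$pvs && n$ps >= 1),
    list("Pathogenic", "Ib", function(n) n$pvs && n$pm >= 2),
    list("Pathogenic", "Id", function(n) n$pvs && n$pp >= 2),
    list("Pathogenic", "Ic", function(n) n$pvs && n$pm >= 1 && n$pp >= 1),
    list("Pathogenic", "II", function(n) n$ps >= 2),
    list("Pathogenic", "IIIa", function(n) n$ps >= 1 && n$pm >= 3),
    list("Pathogenic", "IIIb", function(n) n$ps >= 1 && n$pm >= 2 && n$pp >= 2),
    list("Pathogenic", "IIIc", function(n) n$ps >= 1 && n$pm >= 1 && n$pp >= 4),
    list("Likely_pathogenic", "I", function(n) n$pvs && n$pm >= 1),
    list("Likely_pathogenic", "II", function(n) n$ps >= 1 && n$pm >= 1 && n$pm <= 2),
    list("Likely_pathogenic", "III", function(n) n$ps >= 1 && n$pp >= 2),
    list("Likely_pathogenic", "IV", function(n) n$pm >= 3),
    list("Likely_pathogenic", "V", function(n) n$pm >= 2 && n$pp >= 2),
    list("Likely_pathogenic", "VI", function(n) n$pm >= 1 && n$pp >= 4)
  )
}

#' Combine an ACMG/AMP evidence set into a classification
#'
#' Applies the combining rules in a fixed first-match order: the Pathogenic
#' branch (tiers Ia, Ib, Id, Ic, II, IIIa, IIIb, IIIc), then the
#' Likely-Pathogenic branch (I-VI), then the benign rules (BA1 stand-alone,
#' two strong benign, one strong + one supporting benign, two supporting
#' benign), otherwise VUS.
#'
#' Two conflict-handling modes exist. In `table_faithful` (the default)
#' benign codes co-occurring with a pathogenic-side match are recorded in
#' the rule trace but do not veto the call, matching curated classification
#' tables in which, e.g., `PM1PM2PP2PP3BS3` is still Likely Pathogenic (V).
#' In `strict` mode any benign code alongside a pathogenic-side match
#' yields VUS, the guideline's stated conflict rule. `BA1` is treated as
#' stand-alone Benign in both modes.
#'
#' @param evidence attribute string or character vector of codes.
#' @param mode `"table_faithful"` or `"strict"`.
#' @return object of class `acmg_classification`: list with `klass` (one of
#'   Pathogenic, Likely_pathogenic, VUS, Likely_benign, Benign), `tier`
#'   (subclass for P/LP, `NA` otherwise), and `rule_trace` (tibble of every
#'   rule tested and whether it matched).
#' @export
acmg_combine <- function(evidence, mode = c("table_faithful", "strict")) {
  mode <- match.arg(mode)
  codes <- parse_acmg(evidence)
  n <- acmg_counts(codes)
  trace <- list()
  note <- function(rule, matched) {
    trace[[length(trace) + 1]] <<- tibble::tibble(rule = rule, matched = matched)
  }
  finish <- function(klass, tier) {
    structure(
      list(
        klass = klass, tier = tier,
        attributes = format_acmg(codes),
        rule_trace = dplyr::bind_rows(trace)
      ),
      class = "acmg_classification"
    )
  }

  note("BA1_standalone", n$ba)
  if (n$ba) {
    return(finish("Benign", NA_character_))
  }

  has_benign <- n$bs > 0 || n$bp > 0
  for (rule in acmg_rules()) {
    hit <- rule[[3]](n)
    note(paste0(rule[[1]], "_", rule[[2]]), hit)
    if (hit) {
      if (mode == "strict" && has_benign) {
        note("strict_benign_conflict", TRUE)
        return(finish("VUS", NA_character_))
      }
      return(finish(rule[[1]], rule[[2]]))
    }
  }

  note("Benign_2BS", n$bs >= 2)
  if (n$bs >= 2) {
    return(finish("Benign", NA_character_))
  }
  note("Likely_benign_BS_BP", n$bs >= 1 && n$bp >= 1)
  note("Likely_benign_2BP", n$bp >= 2)
  if ((n$bs >= 1 && n$bp >= 1) || n$bp >= 2) {
    return(finish("Likely_benign", NA_character_))
  }
  finish("VUS", NA_character_)
}

#' @export
print.acmg_classification <- function(x, ...) {
  cat("<acmg_classification> ", x$klass,
    if (!is.na(x$tier)) paste0(" (", x$tier, ")"),
    "  [", x$attributes, "]\n",
    sep = ""
  )
  invisible(x)
}

#' Confidence band of a classification
#'
#' Collapses class + tier into the reporting bands used for carrier and
#' prevalence summaries: `pathogenic` for any Pathogenic call, `lp_high`
#' for Likely Pathogenic tiers I-III (functional or strong evidence),
#' `lp_low` for tiers IV-VI (in-silico-dominated evidence), and `other`
#' for everything else.
#'
#' @param klass classification class, or an `acmg_classification` object.
#' @param tier subclass tier (ignored when `klass` is an object).
#' @return one of `"pathogenic"`, `"lp_high"`, `"lp_low"`, `"other"`.
#' @export
confidence_band <- function(klass, tier = NA_character_) {
  if (inherits(klass, "acmg_classification")) {
    tier <- klass$tier
    klass <- klass$klass
  }
  band1 <- function(k, t) {
    if (k == "Pathogenic") {
      return("pathogenic")
    }
    if (k == "Likely_pathogenic") {
      if (t %in% c("I", "II", "III")) {
        return("lp_high")
      }
      return("lp_low")
    }
    "other"
  }
  mapply(band1, klass, ifelse(is.na(tier), "", tier), USE.NAMES = FALSE)
}

#' Classify a batch of evidence sets
#'
#' @param evidence character vector of attribute strings (or list of code
#'   vectors).
#' @param mode see [acmg_combine()].
#' @return tibble with `attributes`, `klass`, `tier`, `band`, one row per
#'   input, deterministic and order-independent.
#' @export
classify_batch <- function(evidence, mode = "table_faithful") {
  res <- lapply(evidence, acmg_combine, mode = mode)
  tibble::tibble(
    attributes = vapply(res, `[[`, character(1), "attributes"),
    klass = vapply(res, `[[`, character(1), "klass"),
    tier = vapply(res, `[[`, character(1), "tier"),
    band = vapply(res, function(x) confidence_band(x), character(1))
  )
}

#' Attribute-assignment configuration
#'
#' @param pm2_af_max allele frequency strictly below which (or absence) a
#'   variant counts as absent/ultra-rare in a reference dataset (PM2).
#' @param pm2_datasets datasets consulted for PM2; `NULL` means every
#'   `af_<dataset>` column present in the table.
#' @param insilico_k number of in-silico tools that must agree for a
#'   consensus call (PP3 deleterious / BP4 benign); capped at the number of
#'   tools with a prediction available for the variant.
#' @param cadd_cutoff CADD threshold separating a deleterious vote
#'   (strictly above) from a benign vote.
#' @return an `acmg_config` list.
#' @export
acmg_config <- function(pm2_af_max = 1e-4, pm2_datasets = NULL,
                        insilico_k = 2, cadd_cutoff = 15) {
  structure(
    list(
      pm2_af_max = pm2_af_max, pm2_datasets = pm2_datasets,
      insilico_k = insilico_k, cadd_cutoff = cadd_cutoff
    ),
    class = "acmg_config"
  )
}

#' Curated evidence container
#'
#' Holds the hand-curated, non-mechanizable evidence that drives several
#' attribute rules: per-variant functional-study assertions (PS3/BS3 with
#' citation), segregation (PP1), same-residue pathogenic changes (PM5),
#' reputable-source assertions (PP5/BP6), free-form per-variant code
#' overrides, and per-gene mutational hotspot intervals (PM1).
#'
#' @param per_variant tibble with columns `variant_id` and any of
#'   `functional_effect` (`damaging` / `benign_shown` / `none`), `citation`,
#'   `segregation`, `same_residue_pathogenic`, `reputable_pathogenic`,
#'   `reputable_benign`, `add_codes`, `remove_codes` (comma-separated code
#'   strings).
#' @param hotspots tibble with columns `gene`, `start`, `end` (1-based,
#'   closed genomic intervals).
#' @return a `curated_evidence` object.
#' @export
curated_evidence <- function(per_variant = NULL, hotspots = NULL) {
  if (is.null(per_variant)) {
    per_variant <- tibble::tibble(variant_id = character(0))
  }
  per_variant <- tibble::as_tibble(per_variant)
  if (!"variant_id" %in% names(per_variant)) {
    stop("curated per-variant table needs a variant_id column")
  }
  if ("functional_effect" %in% names(per_variant)) {
    damaging <- !is.na(per_variant$functional_effect) &
      per_variant$functional_effect == "damaging"
    cit <- per_variant$citation %||% rep(NA_character_, nrow(per_variant))
    if (any(damaging & (is.na(cit) | cit == ""))) {
      stop("curated damaging functional effect requires a citation")
    }
  }
  if (is.null(hotspots)) {
    hotspots <- tibble::tibble(
      gene = character(0), start = integer(0), end = integer(0)
    )
  }
  structure(
    list(per_variant = tibble::as_tibble(per_variant), hotspots = tibble::as_tibble(hotspots)),
    class = "curated_evidence"
  )
}

curated_row <- function(curated, vid) {
  hit <- which(curated$per_variant$variant_id == vid)
  if (length(hit) == 0) {
    return(NULL)
  }
  as.list(curated$per_variant[hit[1], ])
}

cur_field <- function(row, field, default = NA) {
  if (is.null(row) || is.null(row[[field]])) {
    return(default)
  }
  row[[field]]
}

in_hotspot <- function(curated, gene, pos) {
  h <- curated$hotspots
  any(!is.na(gene) & h$gene == gene & h$start <= pos & h$end >= pos)
}

reputable_pathogenic_terms <- c(
  "Pathogenic", "Likely_pathogenic", "Pathogenic/likely_pathogenic",
  "Pathogenic/Likely_pathogenic"
)

insilico_votes <- function(variant, config) {
  sift <- as.character(variant$sift_call %||% NA)
  poly <- as.character(variant$polyphen_call %||% NA)
  cadd <- variant$cadd_phred %||% NA_real_
  avail <- c(!is.na(sift), !is.na(poly), !is.na(cadd))
  del <- sum(
    isTRUE(!is.na(sift) && sift == "D"),
    isTRUE(!is.na(poly) && poly %in% c("D", "P")),
    isTRUE(!is.na(cadd) && cadd > config$cadd_cutoff)
  )
  ben <- sum(
    isTRUE(!is.na(sift) && sift == "T"),
    isTRUE(!is.na(poly) && poly == "B"),
    isTRUE(!is.na(cadd) && cadd <= config$cadd_cutoff)
  )
  list(n_avail = sum(avail), del = del, ben = ben)
}

#' Assign ACMG/AMP attributes to a variant
#'
#' Deterministic rule evaluation over the variant's annotations, its pLoF
#' call, its gene's panel entry, and curated evidence:
#' * `PVS1`: high-confidence LoF in a gene with an established LoF disease
#'   mechanism.
#' * `PS3` / `BS3`: curated functional studies (damaging / benign shown).
#' * `PM1`: inside a curated mutational hotspot.
#' * `PM2`: absent from, or strictly below `pm2_af_max` in, every
#'   configured reference dataset.
#' * `PM5`: curated same-residue pathogenic change.
#' * `PP1`: curated segregation.
#' * `PP2`: missense in a missense-constrained panel gene.
#' * `PP3` / `BP4`: in-silico consensus (at least `insilico_k` of the
#'   available tools, capped at availability).
#' * `PP5` / `BP6`: curated reputable-source assertion; when no curated
#'   value exists, a ClinVar pathogenic/likely-pathogenic (resp. benign)
#'   significance stands in as the reputable source.
#' * `BP1`: missense in a gene whose established disease mechanism is
#'   truncation.
#' Curated `add_codes` / `remove_codes` overrides are applied last; no
#' assigner ships for PS1/PS2/PS4, PM3/PM4/PM6, PP4, BS1/BS2/BS4 or the
#' remaining BP codes (they are accepted by [acmg_combine()] and can be
#' injected via overrides).
#'
#' @param variant one-row variant tibble (or list).
#' @param lof_call an `lof_call` (see [grade_confidence()]), or `NULL` for
#'   non-LoF variants.
#' @param panel_entry one-row panel tibble for the variant's gene (or
#'   `NULL` if off-panel).
#' @param curated a [curated_evidence()] container.
#' @param config an [acmg_config()].
#' @return character vector of assigned codes (canonical order).
#' @export
assign_attributes <- function(variant, lof_call = NULL, panel_entry = NULL,
                              curated = curated_evidence(),
                              config = acmg_config()) {
  v <- as.list(variant)
  vid <- variant_id(v$chrom, v$pos, v$ref, v$alt)
  row <- curated_row(curated, vid)
  codes <- character(0)
  add <- function(code) codes <<- c(codes, code)

  is_missense <- !is.na(v$consequence %||% NA) && v$consequence == "missense"
  lof_hc <- !is.null(lof_call) && lof_call$confidence == "HC"
  lof_gene <- !is.null(panel_entry) && isTRUE(panel_entry$lof_mechanism)
  constrained <- !is.null(panel_entry) && isTRUE(panel_entry$missense_constrained)

  if (lof_hc && lof_gene) add("PVS1")

  fx <- cur_field(row, "functional_effect", NA_character_)
  if (!is.na(fx) && fx == "damaging") add("PS3")
  if (!is.na(fx) && fx == "benign_shown") add("BS3")

  if (!is.null(v$gene) && in_hotspot(curated, v$gene, as.integer(v$pos))) add("PM1")

  ds <- config$pm2_datasets
  af_cols <- if (is.null(ds)) {
    grep("^af_", names(v), value = TRUE)
  } else {
    paste0("af_", ds)
  }
  afs <- unlist(v[intersect(af_cols, names(v))], use.names = FALSE)
  if (length(afs) == 0 || all(is.na(afs) | afs < config$pm2_af_max)) add("PM2")

  if (isTRUE(cur_field(row, "same_residue_pathogenic", FALSE))) add("PM5")
  if (isTRUE(cur_field(row, "segregation", FALSE))) add("PP1")
  if (is_missense && constrained) add("PP2")

  votes <- insilico_votes(v, config)
  k <- min(config$insilico_k, max(votes$n_avail, 1L))
  if (votes$n_avail > 0 && votes$del >= k) add("PP3")
  if (votes$n_avail > 0 && votes$ben >= k) add("BP4")

  clinvar <- as.character(v$clinvar_sig %||% NA)
  rep_path <- cur_field(row, "reputable_pathogenic", NA)
  if (is.na(rep_path)) rep_path <- !is.na(clinvar) && clinvar %in% reputable_pathogenic_terms
  if (isTRUE(as.logical(rep_path))) add("PP5")
  rep_ben <- cur_field(row, "reputable_benign", NA)
  if (is.na(rep_ben)) {
    rep_ben <- !is.na(clinvar) &&
      clinvar %in% c("Benign", "Likely_benign", "Benign/Likely_benign")
  }
  if (isTRUE(as.logical(rep_ben))) add("BP6")

  if (is_missense && lof_gene) add("BP1")

  extra <- cur_field(row, "add_codes", NA_character_)
  if (!is.na(extra) && nzchar(extra)) {
    codes <- c(codes, parse_acmg(gsub(",", "", extra)))
  }
  drop <- cur_field(row, "remove_codes", NA_character_)
  if (!is.na(drop) && nzchar(drop)) {
    codes <- setdiff(codes, parse_acmg(gsub(",", "", drop)))
  }
  ACMG_CODES[ACMG_CODES %in% codes]
}

#' Assign attributes for a variant table
#'
#' @param variants annotated variant tibble.
#' @param lof_calls tibble as returned by [collect_plof()] (matched by
#'   `variant_id`); variants without a row are treated as non-LoF.
#' @param panel gene panel tibble.
#' @param curated a [curated_evidence()].
#' @param config an [acmg_config()].
#' @return tibble with `variant_id`, `gene` and `attributes` (canonical
#'   concatenated string).
#' @export
assign_attributes_batch <- function(variants, lof_calls = NULL,
                                    panel = default_gene_panel(),
                                    curated = curated_evidence(),
                                    config = acmg_config()) {
  ids <- variant_id(variants$chrom, variants$pos, variants$ref, variants$alt)
  out <- character(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    entry <- NULL
    g <- variants$gene[i]
    if (!is.na(g) && g %in% panel$gene) {
      entry <- panel[panel$gene == g, , drop = FALSE]
    }
    lc <- NULL
    if (!is.null(lof_calls) && ids[i] %in% lof_calls$variant_id) {
      r <- lof_calls[lof_calls$variant_id == ids[i], , drop = FALSE][1, ]
      lc <- structure(
        list(lof_type = r$lof_type, confidence = r$confidence, reasons = character(0)),
        class = "lof_call"
      )
    }
    out[i] <- format_acmg(
      assign_attributes(variants[i, ], lc, entry, curated, config)
    )
  }
  tibble::tibble(variant_id = ids, gene = variants$gene, attributes = out)
}
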