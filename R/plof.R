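# Predicted loss-of-function (pLoF) calling and confidence grading. The
# high/low-confidence heuristic is a deliberate simplification of the
# LOFTEE-style approach: a truncating variant is demoted to low confidence
# when it is likely to escape nonsense-mediated decay (last coding exon or
# within 50 bp upstream of the final exon-exon junction), when a splice
# variant is not at the canonical +/-1,2 intronic positions, or when the
# transcript is not canonical. The rule set is small by design; only the
# HC/LC distinction matters downstream (PVS1 assignment).

LOF_CONSEQUENCES <- c(
  "stop_gained", "stopgain", "frameshift", "frameshift_insertion",
  "frameshift_deletion", "splice_donor", "splice_acceptor", "splicing"
)

# Minimum intron offset over the reference-affected interval; NA when no
# affected base is intronic.
min_intron_offset <- function(tx, pos, ref_len) {
  offs <- vapply(
    seq.int(pos, pos + ref_len - 1L),
    function(p) intron_offset(tx, p), integer(1)
  )
  if (all(is.na(offs))) NA_integer_ else min(offs, na.rm = TRUE)
}

#' Call the loss-of-function type of a variant on a transcript
#'
#' Decides among `stopgain` (a substitution creating a stop codon in the
#' CDS), `frameshift` (an indel whose length is not a multiple of 3 within
#' the CDS), `splice_site` (within `splice_window` bases of an intron
#' boundary) and `none`. Stop-codon detection translates the affected codon
#' against the transcript's stored genomic sequence, strand-aware; when no
#' sequence is attached, the variant's `consequence` annotation is used as
#' a fallback for substitutions.
#'
#' @param variant list or one-row data frame with `chrom`, `pos`, `ref`,
#'   `alt` (and optionally `consequence`).
#' @param tx a [transcript_model()].
#' @param splice_window how far into the intron (bases) a variant still
#'   counts as splice-disrupting. Default 2 (the canonical donor/acceptor
#'   dinucleotide); widen to treat the extended splice region as pLoF.
#' @return one of `"stopgain"`, `"frameshift"`, `"splice_site"`, `"none"`.
#' @export
call_lof_type <- function(variant, tx, splice_window = 2) {
  v <- as.list(variant)
  pos <- as.integer(v$pos)
  ref <- as.character(v$ref)
  alt <- as.character(v$alt)
  span <- tx_span(tx)
  if (!identical(as.character(v$chrom), tx$chrom) ||
    pos + nchar(ref) - 1L < span[1] || pos > span[2]) {
    return("none")
  }

  off <- min_intron_offset(tx, pos, nchar(ref))
  if (!is.na(off) && off <= splice_window) {
    return("splice_site")
  }

  cdsp <- cds_positions(tx)
  affected <- seq.int(pos, pos + nchar(ref) - 1L)

  if (nchar(ref) != nchar(alt)) {
    if (!any(affected %in% cdsp)) {
      return("none")
    }
    if (abs(nchar(ref) - nchar(alt)) %% 3L != 0L) {
      return("frameshift")
    }
    return("none")
  }

  if (nchar(ref) == 1L && pos %in% cdsp) {
    if (is.null(tx$seq)) {
      cons <- as.character(v$consequence %||% NA_character_)
      if (!is.na(cons) && cons %in% c("stop_gained", "stopgain")) {
        return("stopgain")
      }
      return("none")
    }
    i <- match(pos, cdsp)
    codon_idx <- (i - 1L) %/% 3L
    codon_pos <- cdsp[codon_idx * 3L + 1:3]
    if (anyNA(codon_pos)) {
      return("none") # trailing partial codon
    }
    bases <- genomic_base(tx, codon_pos)
    alt_g <- alt
    if (tx$strand == "-") {
      bases <- complement_base(bases)
      alt_g <- complement_base(alt)
    }
    ref_codon <- paste(bases, collapse = "")
    within <- (i - 1L) %% 3L + 1L
    bases[within] <- alt_g
    alt_codon <- paste(bases, collapse = "")
    code <- Biostrings::GENETIC_CODE
    if (!is.na(code[alt_codon]) && code[alt_codon] == "*" &&
      (is.na(code[ref_codon]) || code[ref_codon] != "*")) {
      return("stopgain")
    }
  }
  "none"
}

# Last exon and the NMD-escape window (50 bp upstream of the final
# exon-exon junction), in transcript orientation.
nmd_escape_reasons <- function(tx, pos) {
  n <- length(tx$exon_starts)
  reasons <- character(0)
  if (tx$strand == "+") {
    last <- c(tx$exon_starts[n], tx$exon_ends[n])
    if (n >= 2) {
      junction_window <- c(max(
        tx$exon_starts[n - 1],
        tx$exon_ends[n - 1] - 49L
      ), tx$exon_ends[n - 1])
    }
  } else {
    last <- c(tx$exon_starts[1], tx$exon_ends[1])
    if (n >= 2) {
      junction_window <- c(tx$exon_starts[2], min(
        tx$exon_ends[2],
        tx$exon_starts[2] + 49L
      ))
    }
  }
  if (pos >= last[1] && pos <= last[2]) {
    reasons <- c(reasons, "last_exon")
  } else if (n >= 2 && pos >= junction_window[1] && pos <= junction_window[2]) {
    reasons <- c(reasons, "final_junction_50bp")
  }
  reasons
}

#' Grade the confidence of a loss-of-function call
#'
#' A pLoF call is low confidence (LC) if any of the following fire:
#' truncation in the last coding exon or within 50 bp upstream of the final
#' exon-exon junction (likely NMD escape), a splice variant outside the
#' canonical +/-1,2 intronic positions, or a non-canonical transcript.
#' Otherwise it is high confidence (HC).
#'
#' @inheritParams call_lof_type
#' @param lof_type optional pre-computed type; computed via
#'   [call_lof_type()] when missing.
#' @return an object of class `lof_call`: list with `lof_type`,
#'   `confidence` (`"HC"`, `"LC"` or `"not_lof"`), and `reasons` (the LC
#'   rules that fired).
#' @export
grade_confidence <- function(variant, tx, lof_type = NULL, splice_window = 2) {
  if (is.null(lof_type)) {
    lof_type <- call_lof_type(variant, tx, splice_window = splice_window)
  }
  if (lof_type == "none") {
    return(structure(
      list(lof_type = "none", confidence = "not_lof", reasons = character(0)),
      class = "lof_call"
    ))
  }
  v <- as.list(variant)
  pos <- as.integer(v$pos)
  reasons <- character(0)
  if (!tx$canonical) {
    reasons <- c(reasons, "non_canonical_transcript")
  }
  if (lof_type %in% c("stopgain", "frameshift")) {
    reasons <- c(reasons, nmd_escape_reasons(tx, pos))
  }
  if (lof_type == "splice_site") {
    off <- min_intron_offset(tx, pos, nchar(as.character(v$ref)))
    if (is.na(off) || off > 2L) {
      reasons <- c(reasons, "non_canonical_splice_position")
    }
  }
  structure(
    list(
      lof_type = lof_type,
      confidence = if (length(reasons) > 0) "LC" else "HC",
      reasons = reasons
    ),
    class = "lof_call"
  )
}

#' @export
print.lof_call <- function(x, ...) {
  cat("<lof_call> ", x$lof_type, " / ", x$confidence,
    if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ", "), "]"),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Collect high-confidence pLoF variants in panel genes
#'
#' Runs [call_lof_type()] and [grade_confidence()] for every variant lying
#' in a panel gene with a transcript model and returns the calls. Genes that
#' carry LoF-annotated variants but lack a transcript model are skipped with
#' a warning.
#'
#' @param variants annotated variant tibble.
#' @param panel gene panel tibble (see [load_gene_panel()]).
#' @param transcripts named list (by gene) of [transcript_model()] objects.
#' @param splice_window see [call_lof_type()].
#' @param confidence which confidence classes to return. Default `"HC"`.
#' @return tibble with `variant_id`, `gene`, `lof_type`, `confidence`,
#'   `reasons` for the retained calls.
#' @export
collect_plof <- function(variants, panel, transcripts,
                         splice_window = 2, confidence = "HC") {
  rows <- list()
  for (g in intersect(panel$gene, unique(variants$gene))) {
    sub <- variants[!is.na(variants$gene) & variants$gene == g, , drop = FALSE]
    tx <- transcripts[[g]]
    if (is.null(tx)) {
      if (any(sub$consequence %in% LOF_CONSEQUENCES)) {
        warning("no transcript model for panel gene ", g, "; gene skipped")
      }
      next
    }
    for (i in seq_len(nrow(sub))) {
      call <- grade_confidence(sub[i, ], tx, splice_window = splice_window)
      if (call$lof_type == "none") next
      rows[[length(rows) + 1]] <- tibble::tibble(
        variant_id = variant_id(sub$chrom[i], sub$pos[i], sub$ref[i], sub$alt[i]),
        gene = g,
        lof_type = call$lof_type,
        confidence = call$confidence,
        reasons = paste(call$reasons, collapse = ";")
      )
    }
  }
  out <- if (length(rows) == 0) {
    tibble::tibble(
      variant_id = character(0), gene = character(0),
      lof_type = character(0), confidence = character(0),
      reasons = character(0)
    )
  } else {
    dplyr::bind_rows(rows)
  }
  out[out$confidence %in% confidence, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
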