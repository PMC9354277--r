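# Minimal transcript models: ordered exon intervals, a CDS span, a strand
# and (optionally) the genomic sequence of the locus, enough to decide
# whether a variant truncates the coding sequence and where it falls
# relative to splice junctions. Coordinates are genomic, 1-based, closed.

#' Build a transcript model
#'
#' @param tx_id transcript identifier.
#' @param gene gene symbol the transcript belongs to.
#' @param chrom chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends parallel vectors of exon intervals in
#'   ascending genomic order, non-overlapping.
#' @param cds_start,cds_end genomic CDS span (within the exon span).
#' @param canonical is this the canonical transcript of the gene?
#' @param seq optional genomic plus-strand sequence covering the locus,
#'   as a single string; needed for stop-codon detection.
#' @param seq_offset genomic position of the first base of `seq`.
#' @return object of class `transcript_model`.
#' @export
transcript_model <- function(tx_id, gene, chrom, strand,
                             exon_starts, exon_ends,
                             cds_start, cds_end,
                             canonical = TRUE,
                             seq = NULL, seq_offset = min(exon_starts)) {
  stopifnot(
    length(exon_starts) == length(exon_ends),
    all(exon_ends >= exon_starts),
    strand %in% c("+", "-")
  )
  o <- order(exon_starts)
  exon_starts <- exon_starts[o]
  exon_ends <- exon_ends[o]
  if (length(exon_starts) > 1 &&
    any(exon_starts[-1] <= exon_ends[-length(exon_ends)])) {
    stop("exons must be non-overlapping and ordered")
  }
  if (cds_start < min(exon_starts) || cds_end > max(exon_ends) || cds_start > cds_end) {
    stop("CDS must lie within the exon span")
  }
  structure(
    list(
      tx_id = tx_id, gene = gene, chrom = chrom, strand = strand,
      exon_starts = as.integer(exon_starts), exon_ends = as.integer(exon_ends),
      cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
      canonical = isTRUE(canonical),
      seq = seq, seq_offset = as.integer(seq_offset)
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(
    "<transcript_model> ", x$tx_id, " (", x$gene, ") ", x$chrom, ":",
    min(x$exon_starts), "-", max(x$exon_ends), " strand ", x$strand,
    ", ", length(x$exon_starts), " exons",
    if (!x$canonical) ", non-canonical" else "", "\n",
    sep = ""
  )
  invisible(x)
}

tx_span <- function(tx) c(min(tx$exon_starts), max(tx$exon_ends))

# Introns as genomic intervals (ascending order); empty for single-exon.
tx_introns <- function(tx) {
  n <- length(tx$exon_starts)
  if (n < 2) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = tx$exon_ends[-n] + 1L, end = tx$exon_starts[-1] - 1L)
}

# Genomic positions of the CDS in translation (5'->3') order.
cds_positions <- function(tx) {
  pos <- unlist(mapply(seq.int, tx$exon_starts, tx$exon_ends, SIMPLIFY = FALSE))
  pos <- pos[pos >= tx$cds_start & pos <= tx$cds_end]
  if (tx$strand == "-") rev(pos) else pos
}

# Plus-strand genomic base(s) at position(s) from the stored sequence.
genomic_base <- function(tx, pos) {
  stopifnot(!is.null(tx$seq))
  i <- pos - tx$seq_offset + 1L
  vapply(i, function(j) substr(tx$seq, j, j), character(1))
}

complement_base <- function(b) {
  chartr("ACGTacgt", "TGCAtgca", b)
}

# Distance (1-based) of an intronic position into its intron, measured from
# the nearer boundary; NA if the position is not intronic.
intron_offset <- function(tx, pos) {
  introns <- tx_introns(tx)
  hit <- which(introns$start <= pos & pos <= introns$end)
  if (length(hit) == 0) {
    return(NA_integer_)
  }
  min(pos - introns$start[hit] + 1L, introns$end[hit] - pos + 1L)
}

#' Read transcript models from GFF3/GTF
#'
#' Thin wrapper over `rtracklayer::import()`: exon and CDS features are
#' grouped by their transcript identifier. A `canonical` attribute, when
#' present, marks the canonical transcript; otherwise the first transcript
#' of each gene is taken as canonical.
#'
#' @param path GFF3 or GTF file.
#' @return named list (by gene) of [transcript_model()] objects.
#' @export
read_transcript_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("rtracklayer is required to read GFF3/GTF transcript models")
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  tx_col <- intersect(c("transcript_id", "Parent", "ID"), names(df))[1]
  if (is.na(tx_col)) stop("no transcript identifier attribute in '", path, "'")
  df$tx <- as.character(df[[tx_col]])
  canon_map <- list()
  if ("canonical" %in% names(df)) {
    for (i in which(!is.na(df$canonical))) {
      tid <- if (!is.null(df[["ID"]]) && !is.na(df$ID[i])) as.character(df$ID[i]) else df$tx[i]
      canon_map[[tid]] <- tolower(as.character(df$canonical[i])) %in% c("true", "1", "yes")
    }
  }
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  out <- list()
  for (tx_id in unique(df$tx)) {
    sub <- df[df$tx == tx_id, , drop = FALSE]
    ex <- sub[sub$type == "exon", , drop = FALSE]
    cds <- sub[sub$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0 || nrow(cds) == 0) next
    gene <- if ("gene_id" %in% names(sub)) as.character(sub$gene_id[1]) else tx_id
    canon <- if (!is.null(canon_map[[tx_id]])) {
      canon_map[[tx_id]]
    } else {
      !(gene %in% vapply(out, `[[`, character(1), "gene"))
    }
    out[[length(out) + 1]] <- transcript_model(
      tx_id = tx_id, gene = gene,
      chrom = as.character(ex$seqnames[1]),
      strand = as.character(ex$strand[1]),
      exon_starts = ex$start, exon_ends = ex$end,
      cds_start = min(cds$start), cds_end = max(cds$end),
      canonical = canon
    )
  }
  stats::setNames(out, vapply(out, `[[`, character(1), "gene"))
}
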