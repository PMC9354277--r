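# Loader for the published-table fixtures shipped with the package: the 36
# nonsynonymous and 6 pLoF pathogenic / likely-pathogenic variants with
# their curated attribute strings, the per-variant carrier counts, and the
# genome-scale funnel reference. File digests are frozen here so silent
# fixture edits fail loudly.

FIXTURE_MD5 <- c(
  table1_variants.tsv = "4fbe5d37d7117a7e3c1cc2083fd1afb4",
  table2_variants.tsv = "332cce9a9a786153b84c325a763da551",
  carrier_counts.tsv = "aaa1ad31f8568111de4ce72ec4316f1a",
  funnel_expectations.tsv = "5cc67a7179731ed70aa765262bfd08d7"
)

fixture_path <- function(name) {
  system.file("extdata", name, package = "channelscan", mustWork = TRUE)
}

#' Load the published-table fixtures
#'
#' Returns the curated evidence tables encoding the published pathogenic /
#' likely-pathogenic variant sets: 36 nonsynonymous rows and 6 pLoF rows
#' with gene, HGVS, ACMG/AMP attribute string, printed classification and
#' uniqueness flag; the reported per-variant carrier counts; and the
#' genome-scale filtering funnel (reference only). Fixture files are
#' checksum-verified and structurally validated (42 evidence rows in
#' total).
#'
#' @return list with `nonsyn` (36-row tibble), `plof` (6-row tibble),
#'   `evidence` (both stacked, 42 rows), `carriers` (13-row tibble) and
#'   `funnel` (5-row tibble).
#' @export
load_published_fixtures <- function() {
  for (f in names(FIXTURE_MD5)) {
    got <- unname(tools::md5sum(fixture_path(f)))
    if (!identical(got, unname(FIXTURE_MD5[f]))) {
      stop("fixture checksum mismatch for ", f)
    }
  }
  t1 <- read_tsv_commented(fixture_path("table1_variants.tsv"))
  t2 <- read_tsv_commented(fixture_path("table2_variants.tsv"))
  carriers <- read_tsv_commented(fixture_path("carrier_counts.tsv"))
  funnel <- read_tsv_commented(fixture_path("funnel_expectations.tsv"))
  t1$unique <- as.logical(t1$unique)
  t2$unique <- as.logical(t2$unique)
  if (nrow(t1) != 36 || nrow(t2) != 6) {
    stop("fixture row counts corrupted: expected 36 + 6 evidence rows")
  }
  if (nrow(carriers) != 13 || sum(carriers$n_carriers) != 19) {
    stop("carrier-count fixture corrupted")
  }
  evidence <- dplyr::bind_rows(
    dplyr::mutate(t1, branch = "nonsyn", lof_type = NA_character_),
    dplyr::mutate(t2, branch = "plof")
  )
  list(nonsyn = t1, plof = t2, evidence = evidence, carriers = carriers, funnel = funnel)
}
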