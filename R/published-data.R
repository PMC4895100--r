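#' Published habitat census summary (SILVA SSU Ref v.123)
#'
#' The published per-habitat census of full-length 16S rRNA gene
#' sequences derived from the SILVA SSU Ref v.123 release (July 2015):
#' per fine habitat category, the number of sequences, the number of OTUs
#' at the 3% threshold, and the two coverage statistics in percent, plus
#' the printed totals row per domain. Shipped as reference input for
#' aggregation checks and worked examples.
#'
#' Note: the archaeal fine rows as published sum to 53,471 sequences
#' while the published archaeal total row reads 53,546 (a discrepancy of
#' 75 sequences in the source table). Aggregation checks therefore target
#' the row sums for the coarse categories and the bacterial grand total
#' only.
#'
#' @param domain `"bacteria"`, `"archaea"`, or `"both"`.
#' @param include_total Keep the printed totals row(s)?
#' @return A data frame with columns `domain`, `coarse`, `fine`,
#'   `n_sequences`, `n_otus`, `pct_seq_coverage`, `pct_otu_coverage`.
#' @export
silva123_habitat_census <- function(domain = c("both", "bacteria",
                                               "archaea"),
                                    include_total = FALSE) {
  domain <- match.arg(domain)
  path <- system.file("extdata", "silva123_habitat_census.tsv",
                      package = "ssucensus", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (domain != "both") tab <- tab[tab$domain == domain, , drop = FALSE]
  if (!include_total) tab <- tab[tab$coarse != "Total", , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Published deposition-concentration window (2009--2012)
#'
#' Between 2009 and 2012, 908,190 full-length bacterial sequences were
#' submitted and six submissions from five studies accounted for 550,274
#' of them. Shipped as reference input for the concentration arithmetic.
#'
#' @return A list: `years`, `n_total`, `n_top`, `n_top_submissions`,
#'   `n_top_studies`.
#' @export
silva123_deposition_window <- function() {
  list(
    years = c(2009L, 2012L),
    n_total = 908190L,
    n_top = 550274L,
    n_top_submissions = 6L,
    n_top_studies = 5L
  )
}

#' Share of a window's sequences held by its largest submissions
#'
#' Percentage (rounded to one decimal, matching report conventions) of a
#' deposition window's sequences held by a stated set of top submissions.
#'
#' @param n_top Sequences deposited by the top submissions.
#' @param n_total All sequences deposited in the window.
#' @param digits Decimal places.
#' @return Percentage in `[0, 100]`.
#' @export
submission_share_pct <- function(n_top, n_total, digits = 1L) {
  stopifnot(n_total > 0, n_top >= 0, n_top <= n_total)
  round(100 * n_top / n_total, digits)
}
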