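#' Read a deposited per-sequence census table (figshare format)
#'
#' The census deposits per-domain tables with one row per sequence,
#' carrying the database metadata, taxonomy, OTU assignment and habitat
#' categorization. This reader accepts tab-separated tables shaped that
#' way: a header row with at least `id` and `otu` columns; any of `year`,
#' `submission_id`, `isolation_source`, `strain`, `isolate`,
#' `record_name`, `taxonomy`, `method`, `coarse`, `fine` are picked up
#' when present (missing `method` defaults to `"traditional"`; `phylum`
#' is derived from `taxonomy` when available).
#'
#' @param path Path to the table.
#' @param threshold Distance threshold the `otu` column was generated at
#'   (bookkeeping only).
#' @return A list with `meta` (data frame of the metadata columns) and
#'   `partition` (an `otu_partition` rebuilt from the `otu` column), so
#'   coverage and census statistics can be recomputed directly, e.g.
#'   `coverage_result(abundances(x$partition))`.
#' @export
read_figshare_census <- function(path, threshold = 0.03) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  if (!all(c("id", "otu") %in% names(df))) {
    stop("figshare-format table needs 'id' and 'otu' columns", call. = FALSE)
  }
  if (anyDuplicated(df$id)) {
    stop("duplicate sequence id(s) in ", path, call. = FALSE)
  }
  if (anyNA(df$otu)) {
    stop("missing OTU assignment(s) in ", path, call. = FALSE)
  }
  if ("year" %in% names(df)) df$year <- as.integer(df$year)
  if (!"method" %in% names(df)) df$method <- "traditional"
  df$method[is.na(df$method)] <- "traditional"
  if ("taxonomy" %in% names(df) && !"phylum" %in% names(df)) {
    df$phylum <- taxonomy_rank(df$taxonomy, 2L)
  }
  assignment <- df$otu
  names(assignment) <- df$id
  partition <- structure(
    list(threshold = threshold, assignment = assignment,
         heights = numeric(0)),
    class = "otu_partition"
  )
  meta <- df[, setdiff(names(df), "otu"), drop = FALSE]
  list(meta = meta, partition = partition)
}
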