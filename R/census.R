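#' Build a habitat census table
#'
#' One row per observed habitat category (coarse/fine pair), giving the
#' number of sequences, the number of distinct OTUs touched, and both
#' coverage statistics computed on category-scoped abundances -- a
#' singleton here is an OTU with exactly one sequence *in that category*.
#' A totals row is computed on the unscoped abundances. Because an OTU can
#' span categories, per-category OTU counts need not sum to the total.
#'
#' @param partition An `otu_partition` covering every sequence in `meta`.
#' @param meta Metadata data frame with an `id` column.
#' @param labels Data frame with `coarse` and `fine` columns, one row per
#'   row of `meta` (e.g. from [assign_environment()]).
#' @return A data frame with columns `coarse`, `fine`, `n_sequences`,
#'   `n_otus`, `goods_coverage`, `otu_coverage` (coverages as fractions;
#'   see [census_report()] for the percent presentation), ending in a
#'   totals row.
#' @export
build_census_table <- function(partition, meta, labels) {
  stopifnot(inherits(partition, "otu_partition"), is.data.frame(meta),
            "id" %in% names(meta), is.data.frame(labels),
            all(c("coarse", "fine") %in% names(labels)),
            nrow(meta) == nrow(labels))
  missing <- setdiff(meta$id, names(partition$assignment))
  if (length(missing) > 0L) {
    stop("sequence(s) missing from partition: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  hier <- environment_hierarchy()
  key <- paste(labels$coarse, labels$fine, sep = "\r")
  hier_key <- paste(hier$coarse, hier$fine, sep = "\r")
  bad <- setdiff(unique(key), hier_key)
  if (length(bad) > 0L) {
    stop("label(s) outside the habitat hierarchy: ",
         paste(gsub("\r", "/", bad), collapse = ", "), call. = FALSE)
  }
  observed <- hier[hier_key %in% key, , drop = FALSE]
  rows <- lapply(seq_len(nrow(observed)), function(r) {
    scope <- meta$id[labels$coarse == observed$coarse[r] &
                       labels$fine == observed$fine[r]]
    cv <- coverage_result(abundances(partition, scope))
    data.frame(coarse = observed$coarse[r], fine = observed$fine[r],
               n_sequences = cv$n_sequences, n_otus = cv$n_otus,
               goods_coverage = cv$goods_coverage,
               otu_coverage = cv$otu_coverage, stringsAsFactors = FALSE)
  })
  cv <- coverage_result(abundances(partition, meta$id))
  total <- data.frame(coarse = "Total", fine = "",
                      n_sequences = cv$n_sequences, n_otus = cv$n_otus,
                      goods_coverage = cv$goods_coverage,
                      otu_coverage = cv$otu_coverage,
                      stringsAsFactors = FALSE)
  rbind(do.call(rbind, rows), total)
}

#' Aggregate a census table to coarse categories
#'
#' Sums the fine-row sequence counts within each coarse category (the
#' totals row, if present, is excluded).
#'
#' @param table A census table (from [build_census_table()],
#'   [census_report()] or [silva123_habitat_census()]).
#' @return Named numeric vector: coarse category -> total sequences.
#' @export
coarse_aggregate <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("coarse", "fine", "n_sequences") %in% names(table)))
  body <- table[table$coarse != "Total", , drop = FALSE]
  if (nrow(body) == 0L) return(structure(numeric(0), names = character(0)))
  tapply(body$n_sequences, body$coarse, sum)[unique(body$coarse)]
}

#' Percent presentation of a census table
#'
#' @param table Output of [build_census_table()].
#' @param digits Decimal places for the percent columns.
#' @return The table with coverages as `pct_seq_coverage` /
#'   `pct_otu_coverage`, rounded.
#' @export
census_report <- function(table, digits = 1L) {
  stopifnot(all(c("goods_coverage", "otu_coverage") %in% names(table)))
  out <- table
  out$pct_seq_coverage <- round(100 * out$goods_coverage, digits)
  out$pct_otu_coverage <- round(100 * out$otu_coverage, digits)
  out$goods_coverage <- NULL
  out$otu_coverage <- NULL
  out
}

#' Sequences deposited per year
#'
#' @param meta Metadata data frame with a `year` column.
#' @return Data frame `year`, `n` (known years only, ascending), with
#'   attribute `n_unknown` counting records without a year.
#' @export
sequences_per_year <- function(meta) {
  stopifnot(is.data.frame(meta), "year" %in% names(meta))
  known <- meta$year[!is.na(meta$year)]
  tab <- table(known)
  out <- data.frame(year = as.integer(names(tab)), n = as.integer(tab))
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unknown") <- sum(is.na(meta$year))
  out
}

#' New OTUs per discovery year
#'
#' Each OTU is dated by the minimum deposition year among its member
#' sequences; counts of OTUs first observed per year. OTUs whose members
#' all lack a year are tallied separately.
#'
#' @param partition An `otu_partition`.
#' @param meta Metadata data frame with `id` and `year` columns.
#' @return Data frame `year`, `n`, with attribute `n_unknown_otus`.
#' @export
new_otus_per_year <- function(partition, meta) {
  stopifnot(inherits(partition, "otu_partition"), is.data.frame(meta),
            all(c("id", "year") %in% names(meta)))
  otu <- partition$assignment[meta$id]
  if (anyNA(otu)) {
    stop("sequence(s) missing from partition: ",
         paste(utils::head(meta$id[is.na(otu)], 5L), collapse = ", "),
         call. = FALSE)
  }
  year_min <- tapply(meta$year, otu, function(y) {
    y <- y[!is.na(y)]
    if (length(y) == 0L) NA_integer_ else min(y)
  })
  known <- year_min[!is.na(year_min)]
  tab <- table(known)
  out <- data.frame(year = as.integer(names(tab)), n = as.integer(tab))
  out <- out[order(out$year), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unknown_otus") <- sum(is.na(year_min))
  out
}

#' Submissions responsible for half of a year's sequences
#'
#' The minimal number `k` of submissions such that the `k` largest
#' submissions of the year hold at least 50% of that year's sequences
#' (largest first; ties broken by submission id).
#'
#' @param meta Metadata data frame with `year` and `submission_id`.
#' @param year Deposition year to evaluate.
#' @return Integer `k`.
#' @export
submissions_for_half <- function(meta, year) {
  stopifnot(is.data.frame(meta),
            all(c("year", "submission_id") %in% names(meta)))
  rows <- meta[!is.na(meta$year) & meta$year == year, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no records deposited in ", year, call. = FALSE)
  }
  rows <- rows[!is.na(rows$submission_id), , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no submission ids recorded for ", year, call. = FALSE)
  }
  sizes <- table(rows$submission_id)
  ord <- order(-as.integer(sizes), names(sizes), method = "radix")
  cum <- cumsum(as.integer(sizes)[ord])
  as.integer(which(cum >= sum(sizes) / 2)[1L])
}

#' Phylum deposition-rate ratios around a pivot year
#'
#' Splits records into those deposited up to and including `cutoff_year`
#' and those deposited after it, computes each phylum's share of its
#' domain's sequences within each period, and reports the fold change of
#' shares (after / before). Phyla absent before the pivot have an
#' undefined fold and are flagged rather than dropped.
#'
#' @param meta Metadata data frame (one domain) with `year` and `phylum`.
#' @param cutoff_year Pivot year (records `<= cutoff_year` form the
#'   "before" period).
#' @param min_sequences Minimum total sequences for a phylum to be marked
#'   reportable (`meets_min`); all phyla are retained in the output.
#' @return Data frame: `phylum`, `n_before`, `n_after`, `n_total`,
#'   `share_before`, `share_after`, `fold`, `log2_fold`, `undefined`,
#'   `meets_min`.
#' @export
phylum_rate_ratio <- function(meta, cutoff_year = 2006L,
                              min_sequences = 1000L) {
  stopifnot(is.data.frame(meta), all(c("year", "phylum") %in% names(meta)))
  rows <- meta[!is.na(meta$year) & !is.na(meta$phylum), , drop = FALSE]
  before <- rows$year <= cutoff_year
  phyla <- sort(unique(rows$phylum))
  n_before <- vapply(phyla, function(p) sum(before & rows$phylum == p),
                     numeric(1))
  n_after <- vapply(phyla, function(p) sum(!before & rows$phylum == p),
                    numeric(1))
  tot_before <- sum(before)
  tot_after <- sum(!before)
  share_before <- if (tot_before > 0) n_before / tot_before else
    rep(NA_real_, length(phyla))
  share_after <- if (tot_after > 0) n_after / tot_after else
    rep(NA_real_, length(phyla))
  undefined <- is.na(share_before) | share_before == 0
  fold <- ifelse(undefined, NA_real_, share_after / share_before)
  out <- data.frame(
    phylum = phyla,
    n_before = as.integer(n_before), n_after = as.integer(n_after),
    n_total = as.integer(n_before + n_after),
    share_before = share_before, share_after = share_after,
    fold = fold, log2_fold = log2(fold),
    undefined = undefined,
    meets_min = n_before + n_after >= min_sequences,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Cultured census by phylum
#'
#' Per phylum: the percentage of sequences that come from cultured
#' organisms, and the percentage of the phylum's OTUs containing at least
#' one cultured sequence.
#'
#' @param partition An `otu_partition`.
#' @param meta Metadata data frame with `id`, `phylum`, and either a
#'   logical `cultured` column or the `strain` / `isolate` /
#'   `record_name` columns that [flag_cultured()] consumes.
#' @return Data frame: `phylum`, `n_sequences`, `n_otus`,
#'   `pct_sequences_cultured`, `pct_otus_with_cultured_rep`.
#' @export
cultured_summary <- function(partition, meta) {
  stopifnot(inherits(partition, "otu_partition"), is.data.frame(meta),
            all(c("id", "phylum") %in% names(meta)))
  cultured <- if ("cultured" %in% names(meta)) {
    as.logical(meta$cultured)
  } else {
    flag_cultured(meta)
  }
  otu <- partition$assignment[meta$id]
  if (anyNA(otu)) {
    stop("sequence(s) missing from partition", call. = FALSE)
  }
  rows <- !is.na(meta$phylum)
  phyla <- sort(unique(meta$phylum[rows]))
  out <- lapply(phyla, function(p) {
    sel <- rows & meta$phylum == p
    otus <- unique(otu[sel])
    cult_otus <- unique(otu[sel & cultured])
    data.frame(
      phylum = p,
      n_sequences = sum(sel),
      n_otus = length(otus),
      pct_sequences_cultured = 100 * sum(sel & cultured) / sum(sel),
      pct_otus_with_cultured_rep = 100 * length(cult_otus) / length(otus),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Cross-method OTU overlap
#'
#' For each ordered pair of recovery methods (A, B != A): the percentage
#' of OTUs containing at least one A-recovered sequence that also contain
#' at least one B-recovered sequence. The diagonal (A, A) is the
#' percentage of A's OTUs containing sequences from no other method --
#' OTUs found only by A.
#'
#' @param partition An `otu_partition`.
#' @param meta Metadata data frame with `id` and `method`.
#' @return A square numeric matrix (percentages) over the methods present
#'   in `meta`, rows = method A, columns = method B.
#' @export
method_overlap <- function(partition, meta) {
  stopifnot(inherits(partition, "otu_partition"), is.data.frame(meta),
            all(c("id", "method") %in% names(meta)))
  otu <- partition$assignment[meta$id]
  if (anyNA(otu)) {
    stop("sequence(s) missing from partition", call. = FALSE)
  }
  methods <- intersect(METHOD_LEVELS, unique(meta$method))
  otus_of <- lapply(methods, function(m) unique(otu[meta$method == m]))
  names(otus_of) <- methods
  k <- length(methods)
  out <- matrix(NA_real_, k, k, dimnames = list(methods, methods))
  for (a in methods) {
    na <- length(otus_of[[a]])
    if (na == 0L) next
    for (b in methods) {
      if (a == b) {
        others <- unique(unlist(otus_of[setdiff(methods, a)]))
        out[a, b] <- 100 * sum(!otus_of[[a]] %in% others) / na
      } else {
        out[a, b] <- 100 * sum(otus_of[[a]] %in% otus_of[[b]]) / na
      }
    }
  }
  out
}
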