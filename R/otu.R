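#' Average-neighbor clustering into OTUs
#'
#' Agglomerative clustering where the distance between two clusters is the
#' arithmetic mean of all cross-cluster pairwise distances (average
#' linkage). The closest pair of clusters is merged repeatedly while the
#' merge distance is at most `max(thresholds)`; the partition in effect at
#' each requested threshold (all merges at distance `<=` that threshold,
#' inclusive) is returned.
#'
#' Determinism: when several candidate merges share the minimum distance,
#' the pair whose lexicographically smallest member id is least (then the
#' second id) is merged first, so results do not depend on storage order.
#'
#' For a sparse store, thresholds above the cutoff are refused; a
#' cross-pair absent from the store (true distance above the cutoff) is
#' scored as 1.0 when forming merge means, an upper bound that can only
#' defer merges, never create them.
#'
#' @param store A `distance_store` from [build_distance_store()].
#' @param thresholds Distance thresholds, sorted ascending.
#' @return A named list of `otu_partition` objects, one per threshold.
#'   Each has `$threshold`, `$assignment` (named character: sequence id ->
#'   OTU label) and `$heights` (the merge heights used).
#' @examples
#' seqs <- aligned_seqs(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC",
#'                        c = "AATTTTAAAA"), "bacteria")
#' st <- build_distance_store(seqs)
#' average_neighbor_cluster(st, c(0.03, 0.5))
#' @export
average_neighbor_cluster <- function(store, thresholds) {
  stopifnot(inherits(store, "distance_store"))
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0L) stop("no thresholds given", call. = FALSE)
  if (is.unsorted(thresholds, strictly = FALSE)) {
    stop("thresholds must be sorted ascending", call. = FALSE)
  }
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(store$sparse_cutoff) &&
      max(thresholds) > store$sparse_cutoff) {
    stop("threshold ", max(thresholds), " exceeds the sparse cutoff ",
         store$sparse_cutoff, "; rebuild the store with a larger cutoff",
         call. = FALSE)
  }
  n <- store$n
  ids <- store$ids
  t_max <- max(thresholds)

  merges <- an_merge_sequence(store, t_max)

  out <- lapply(thresholds, function(t) {
    member <- an_cut(n, merges, t)
    otu_partition(ids, member, t, merges$height)
  })
  names(out) <- vapply(thresholds, as.character, character(1))
  out
}

# Run the merge loop up to height t_max; returns parallel vectors a, b
# (cluster representatives being merged, as current member indices) and
# height. Heights are forced non-decreasing (running max) so cutting at
# any threshold yields nested partitions.
an_merge_sequence <- function(store, t_max) {
  n <- store$n
  ids <- store$ids
  D <- dist_matrix(store, fill = 1.0)
  diag(D) <- Inf
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  minid <- ids                      # lexicographically smallest member id
  rep_a <- integer(0); rep_b <- integer(0); height <- numeric(0)
  n_active <- n
  while (n_active > 1L) {
    d_min <- min(D)               # inactive rows/cols are Inf
    if (d_min > t_max) break
    hit <- which(D == d_min, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    if (nrow(hit) > 1L) {
      key1 <- pmin(minid[hit[, 1L]], minid[hit[, 2L]])
      key2 <- pmax(minid[hit[, 1L]], minid[hit[, 2L]])
      ord <- order(key1, key2, method = "radix")
      hit <- hit[ord[1L], , drop = FALSE]
    }
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    rep_a <- c(rep_a, i); rep_b <- c(rep_b, j)
    height <- c(height, d_min)
    # Lance-Williams update for average linkage (size-weighted mean keeps
    # the matrix equal to the true mean of cross-pair distances)
    others <- which(active); others <- others[others != i & others != j]
    if (length(others) > 0L) {
      newd <- (size[i] * D[i, others] + size[j] * D[j, others]) /
        (size[i] + size[j])
      D[i, others] <- newd
      D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    minid[i] <- min(minid[i], minid[j])
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
    n_active <- n_active - 1L
  }
  list(a = rep_a, b = rep_b, height = cummax(height))
}

# Union-find replay of merges with height <= t; returns membership vector.
an_cut <- function(n, merges, t) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  take <- which(merges$height <= t)
  for (k in take) {
    ra <- find(merges$a[k]); rb <- find(merges$b[k])
    if (ra != rb) parent[rb] <- ra
  }
  vapply(seq_len(n), find, integer(1))
}

#' Construct an OTU partition
#'
#' Assembles the partition object from a membership vector, labelling OTUs
#' `"OTU"` plus the zero-padded rank by descending abundance (ties broken
#' by smallest member id).
#'
#' @param ids Sequence ids, in index order.
#' @param member Integer membership vector parallel to `ids`.
#' @param threshold The distance threshold the partition corresponds to.
#' @param heights Merge heights (optional bookkeeping).
#' @return An `otu_partition`.
#' @export
otu_partition <- function(ids, member, threshold, heights = numeric(0)) {
  stopifnot(length(ids) == length(member), !anyDuplicated(ids))
  groups <- split(as.character(ids), member)
  sizes <- lengths(groups)
  first_id <- vapply(groups, min, character(1))
  ord <- order(-sizes, first_id, method = "radix")
  width <- nchar(as.character(length(groups)))
  labels <- sprintf("OTU%0*d", width, seq_along(groups))
  assignment <- character(length(ids))
  names(assignment) <- ids
  for (r in seq_along(ord)) {
    assignment[groups[[ord[r]]]] <- labels[r]
  }
  structure(
    list(threshold = threshold, assignment = assignment, heights = heights),
    class = "otu_partition"
  )
}

#' @export
print.otu_partition <- function(x, ...) {
  cat("<otu_partition> threshold ", format(x$threshold), ": ",
      length(unique(x$assignment)), " OTUs over ",
      length(x$assignment), " sequences\n", sep = "")
  invisible(x)
}

#' OTU abundances, optionally restricted to a scope
#'
#' Counts the sequences of each OTU, optionally restricted to a subset of
#' sequence ids (an environment category, a recovery method, a deposition
#' period, ...). OTUs with no in-scope sequence are omitted, so all counts
#' are positive and sum to the number of in-scope sequences.
#'
#' @param partition An `otu_partition`.
#' @param scope Character vector of sequence ids to restrict to, or `NULL`
#'   for all sequences.
#' @return Named integer vector of per-OTU counts (names = OTU labels).
#' @export
abundances <- function(partition, scope = NULL) {
  stopifnot(inherits(partition, "otu_partition"))
  assignment <- partition$assignment
  if (!is.null(scope)) {
    scope <- as.character(scope)
    unknown <- setdiff(scope, names(assignment))
    if (length(unknown) > 0L) {
      stop("scope id(s) not in partition: ",
           paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
    }
    assignment <- assignment[scope]
  }
  if (length(assignment) == 0L) {
    return(structure(integer(0), names = character(0)))
  }
  tab <- table(assignment)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts
}

#' Write / read OTU partitions in list format
#'
#' One row per OTU per threshold: `threshold<TAB>label<TAB>size<TAB>ids`
#' with ids comma-joined -- the "list"-style format common to OTU tools.
#'
#' @param partitions A named list of `otu_partition` objects (as returned
#'   by [average_neighbor_cluster()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_otu_list <- function(partitions, path) {
  if (inherits(partitions, "otu_partition")) partitions <- list(partitions)
  rows <- lapply(partitions, function(p) {
    groups <- split(names(p$assignment), p$assignment)
    data.frame(
      threshold = format(p$threshold, trim = TRUE),
      label = names(groups),
      size = lengths(groups),
      ids = vapply(groups, function(g) paste(sort(g), collapse = ","),
                   character(1)),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_otu_list
#' @export
read_otu_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("threshold", "label", "size", "ids") %in% names(df)))
  out <- lapply(split(df, df$threshold), function(block) {
    ids <- strsplit(block$ids, ",", fixed = TRUE)
    assignment <- rep(block$label, lengths(ids))
    names(assignment) <- unlist(ids)
    structure(
      list(threshold = as.numeric(block$threshold[1L]),
           assignment = assignment, heights = numeric(0)),
      class = "otu_partition"
    )
  })
  out[order(as.numeric(names(out)))]
}
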