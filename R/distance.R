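#' Uncorrected pairwise distance between two aligned sequences
#'
#' Distance is the number of differences over the number of compared
#' positions, walking the shared alignment columns under this convention:
#'
#' * columns where both sequences are gapped are skipped entirely;
#' * a maximal run of columns where one and the same sequence is gapped
#'   counts as one difference and one compared position, regardless of its
#'   length (gap open, not gap extend);
#' * columns where both sequences have a base count one compared position,
#'   and one difference when the bases differ;
#' * terminal gap runs (columns before one sequence's first base or after
#'   its last) are skipped unless `penalize_terminal_gaps` is `TRUE`, in
#'   which case they are scored like internal runs.
#'
#' U and T are treated as the same character. Ambiguity codes (anything
#' other than A, C, G, T, U) mismatch every character including
#' themselves.
#'
#' @param a,b Gapped sequences (character scalars, optionally named by
#'   their accession) of equal gapped length.
#' @param penalize_terminal_gaps Score terminal gap runs as differences?
#' @return Distance in `[0, 1]`.
#' @examples
#' pairwise_distance("AC--GT", "ACTAGT") # one gap run over 5 positions
#' @export
pairwise_distance <- function(a, b, penalize_terminal_gaps = FALSE) {
  id_a <- if (!is.null(names(a))) names(a)[1L] else "a"
  id_b <- if (!is.null(names(b))) names(b)[1L] else "b"
  ca <- prep_chars(a)
  cb <- prep_chars(b)
  if (length(ca) != length(cb)) {
    stop("gapped lengths differ: '", id_a, "' has ", length(ca), ", '",
         id_b, "' has ", length(cb), call. = FALSE)
  }
  pairwise_distance_core(ca, cb, penalize_terminal_gaps, id_a, id_b)
}

# uppercase character vector with U folded to T
prep_chars <- function(x) {
  ch <- strsplit(toupper(as.character(x)[1L]), "", fixed = TRUE)[[1L]]
  ch[ch == "U"] <- "T"
  ch
}

pairwise_distance_core <- function(ca, cb, penalize_terminal_gaps,
                                   id_a, id_b) {
  ga <- ca %in% GAP_CHARS
  gb <- cb %in% GAP_CHARS
  keep <- !(ga & gb)
  ca <- ca[keep]; cb <- cb[keep]
  ga <- ga[keep]; gb <- gb[keep]
  n <- length(ca)
  if (n == 0L) {
    stop("no comparable positions between '", id_a, "' and '", id_b, "'",
         call. = FALSE)
  }
  # 0 = both bases, 1 = gap in a, 2 = gap in b
  state <- integer(n)
  state[ga] <- 1L
  state[gb] <- 2L
  if (!penalize_terminal_gaps) {
    first_a <- which(!ga)[1L]; last_a <- tail_which(!ga)
    first_b <- which(!gb)[1L]; last_b <- tail_which(!gb)
    if (is.na(first_a) || is.na(first_b)) {
      stop("no comparable positions between '", id_a, "' and '", id_b, "'",
           call. = FALSE)
    }
    lo <- max(first_a, first_b)
    hi <- min(last_a, last_b)
    if (lo > hi) {
      stop("no comparable positions between '", id_a, "' and '", id_b, "'",
           call. = FALSE)
    }
    idx <- lo:hi
    state <- state[idx]; ca <- ca[idx]; cb <- cb[idx]
  }
  base_cols <- state == 0L
  # ambiguity codes mismatch everything, including an identical code
  ambig <- !(ca %in% c("A", "C", "G", "T")) | !(cb %in% c("A", "C", "G", "T"))
  mismatch <- base_cols & (ca != cb | ambig)
  r <- rle(state)
  gap_runs <- sum(r$values != 0L)
  compared <- sum(base_cols) + gap_runs
  if (compared == 0L) {
    stop("no comparable positions between '", id_a, "' and '", id_b, "'",
         call. = FALSE)
  }
  (sum(mismatch) + gap_runs) / compared
}

tail_which <- function(x) {
  w <- which(x)
  if (length(w) == 0L) NA_integer_ else w[length(w)]
}

#' Build a pairwise distance store
#'
#' Computes all pairwise distances of a collection with
#' [pairwise_distance()]. When `sparse_cutoff` is given, pairs with
#' distance above the cutoff are omitted from the store (the usual sparse
#' "column format" economy); clustering then refuses thresholds above the
#' cutoff rather than approximating.
#'
#' @param seqs An [aligned_seqs] collection of at least 2 sequences.
#' @param sparse_cutoff Largest distance stored, or `NULL` for a dense
#'   store.
#' @param penalize_terminal_gaps Passed to [pairwise_distance()].
#' @return A `distance_store`: ids, the `(i, j, d)` entries with `i < j`,
#'   and the cutoff.
#' @export
build_distance_store <- function(seqs, sparse_cutoff = NULL,
                                 penalize_terminal_gaps = FALSE) {
  stopifnot(inherits(seqs, "aligned_seqs"))
  n <- length(seqs)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (!is.null(sparse_cutoff)) {
    stopifnot(is.numeric(sparse_cutoff), length(sparse_cutoff) == 1L,
              sparse_cutoff >= 0, sparse_cutoff <= 1)
  }
  ids <- names(seqs)
  chars <- lapply(unclass(seqs), prep_chars)
  m <- n * (n - 1L) / 2L
  ii <- integer(m); jj <- integer(m); dd <- numeric(m)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      ii[k] <- i; jj[k] <- j
      dd[k] <- pairwise_distance_core(chars[[i]], chars[[j]],
                                      penalize_terminal_gaps,
                                      ids[i], ids[j])
    }
  }
  if (!is.null(sparse_cutoff)) {
    keep <- dd <= sparse_cutoff
    ii <- ii[keep]; jj <- jj[keep]; dd <- dd[keep]
  }
  distance_store(ids, ii, jj, dd, sparse_cutoff)
}

#' Construct a distance store from parts
#'
#' @param ids Sequence ids, in index order.
#' @param i,j Integer indices with `i < j` elementwise.
#' @param d Distances in `[0, 1]`.
#' @param sparse_cutoff Cutoff the store was built with, or `NULL`.
#' @return A `distance_store` object.
#' @export
distance_store <- function(ids, i, j, d, sparse_cutoff = NULL) {
  stopifnot(length(i) == length(j), length(j) == length(d),
            all(i < j), all(i >= 1L), all(j <= length(ids)),
            all(d >= 0), all(d <= 1), !anyDuplicated(ids))
  if (!is.null(sparse_cutoff) && any(d > sparse_cutoff)) {
    stop("stored distance exceeds the sparse cutoff", call. = FALSE)
  }
  structure(
    list(n = length(ids), ids = as.character(ids),
         i = as.integer(i), j = as.integer(j), d = as.numeric(d),
         sparse_cutoff = sparse_cutoff),
    class = "distance_store"
  )
}

#' @export
print.distance_store <- function(x, ...) {
  cat("<distance_store> ", x$n, " sequences, ", length(x$d), " entries",
      sep = "")
  if (!is.null(x$sparse_cutoff)) {
    cat(" (sparse, cutoff ", x$sparse_cutoff, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Materialize a distance store as a full matrix
#'
#' @param store A `distance_store`.
#' @param fill Value for pairs absent from a sparse store (their true
#'   distance exceeds the cutoff). Default `NA`.
#' @return A symmetric `n x n` matrix with zero diagonal, dimnames = ids.
#' @export
dist_matrix <- function(store, fill = NA_real_) {
  stopifnot(inherits(store, "distance_store"))
  n <- store$n
  m <- matrix(fill, n, n, dimnames = list(store$ids, store$ids))
  diag(m) <- 0
  m[cbind(store$i, store$j)] <- store$d
  m[cbind(store$j, store$i)] <- store$d
  m
}

#' Write / read a distance store as 3-column text
#'
#' The common sparse "column format": `id_i<TAB>id_j<TAB>distance`, no
#' header. The reader needs the full id set (sequences distant from
#' everything may appear in no row of a sparse file).
#'
#' @param store A `distance_store`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_distance_store <- function(store, path) {
  stopifnot(inherits(store, "distance_store"))
  df <- data.frame(id_i = store$ids[store$i], id_j = store$ids[store$j],
                   distance = store$d)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @param ids Full id set, in index order.
#' @param sparse_cutoff Cutoff the file was written with, or `NULL`.
#' @rdname write_distance_store
#' @export
read_distance_store <- function(path, ids, sparse_cutoff = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(distance_store(ids, integer(0), integer(0), numeric(0),
                          sparse_cutoff))
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id_i", "id_j", "distance"))
  i <- match(df$id_i, ids)
  j <- match(df$id_j, ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(df$id_i[is.na(i)], df$id_j[is.na(j)]))
    stop("distance file references unknown id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  swap <- i > j
  tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  distance_store(ids, i, j, df$distance, sparse_cutoff)
}
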