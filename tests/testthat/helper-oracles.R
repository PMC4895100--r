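# Independent oracles: deliberately naive re-implementations used only to
# check the package's faster/structured code paths.

# Column-walking distance oracle: explicit state machine over alignment
# columns, independent of the vectorized implementation.
oracle_distance <- function(a, b, penalize_terminal_gaps = FALSE) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  ca[ca == "U"] <- "T"
  cb[cb == "U"] <- "T"
  gap <- c("-", ".")
  keep <- !(ca %in% gap & cb %in% gap)
  ca <- ca[keep]; cb <- cb[keep]
  if (!penalize_terminal_gaps) {
    ia <- range(which(!ca %in% gap)); ib <- range(which(!cb %in% gap))
    lo <- max(ia[1], ib[1]); hi <- min(ia[2], ib[2])
    if (lo > hi) stop("no comparable positions")
    ca <- ca[lo:hi]; cb <- cb[lo:hi]
  }
  diffs <- 0L; compared <- 0L
  in_run <- 0L  # 0 none, 1 gap in a, 2 gap in b
  for (k in seq_along(ca)) {
    ga <- ca[k] %in% gap; gb <- cb[k] %in% gap
    if (ga || gb) {
      run <- if (ga) 1L else 2L
      if (run != in_run) {
        diffs <- diffs + 1L
        compared <- compared + 1L
      }
      in_run <- run
    } else {
      in_run <- 0L
      compared <- compared + 1L
      canonical <- ca[k] %in% c("A", "C", "G", "T") &&
        cb[k] %in% c("A", "C", "G", "T")
      if (!canonical || ca[k] != cb[k]) diffs <- diffs + 1L
    }
  }
  if (compared == 0L) stop("no comparable positions")
  diffs / compared
}

# Brute-force average linkage: recomputes every cross-cluster mean from
# the original matrix at every step (no Lance-Williams update). Same
# deterministic tie rule as the package (least smallest-member id).
oracle_average_linkage <- function(D, ids, t) {
  clusters <- as.list(seq_along(ids))
  repeat {
    k <- length(clusters)
    if (k == 1L) break
    best <- NULL; best_d <- Inf; best_key <- NULL
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        key <- sort(c(min(ids[clusters[[i]]]), min(ids[clusters[[j]]])))
        if (d < best_d ||
            (d == best_d && (key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))) {
          best_d <- d; best <- c(i, j); best_key <- key
        }
      }
    }
    if (best_d > t) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  member <- integer(length(ids))
  for (g in seq_along(clusters)) member[clusters[[g]]] <- g
  member
}

# Canonical form of a partition: set of sorted member-id vectors, ordered
# by first member, so labelings can be compared as partitions.
canonical_partition <- function(assignment) {
  groups <- lapply(split(names(assignment), assignment), sort)
  names(groups) <- NULL
  groups[order(vapply(groups, `[`, character(1), 1L))]
}

# Exhaustive rarefaction: mean richness over all C(N, n) subsamples.
oracle_rarefaction_enum <- function(ab, n) {
  pool <- rep(seq_along(ab), ab)
  subs <- utils::combn(length(pool), n)
  mean(apply(subs, 2, function(idx) length(unique(pool[idx]))))
}

# Random gapped sequences sharing one alignment length.
random_gapped_seqs <- function(n, len = 30, p_gap = 0.15,
                               alphabet = c("A", "C", "G", "T")) {
  x <- vapply(seq_len(n), function(i) {
    ch <- sample(alphabet, len, replace = TRUE)
    gaps <- stats::runif(len) < p_gap
    ch[gaps] <- sample(c("-", "."), sum(gaps), replace = TRUE)
    if (all(ch %in% c("-", "."))) ch[sample.int(len, 2)] <- "A"
    paste(ch, collapse = "")
  }, character(1))
  names(x) <- sprintf("s%02d", seq_len(n))
  aligned_seqs(x, "bacteria")
}

# Random abundance vector (counts >= 1).
random_abundances <- function(max_otus = 12, max_count = 8) {
  s <- sample.int(max_otus, 1)
  counts <- sample.int(max_count, s, replace = TRUE)
  names(counts) <- sprintf("OTU%02d", seq_len(s))
  counts
}
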