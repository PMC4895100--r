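#' Good's coverage of an abundance vector
#'
#' `1 - n1 / Nt`, where `n1` is the number of singleton OTUs (represented
#' by exactly one sequence in the scope at hand) and `Nt` the total number
#' of sequences: the estimated probability that the next sequence sampled
#' belongs to an already-observed OTU.
#'
#' @param ab Named numeric vector of per-OTU counts (all `>= 1`).
#' @return Fraction in `[0, 1]`.
#' @export
goods_coverage <- function(ab) {
  check_abundances(ab)
  1 - sum(ab == 1) / sum(ab)
}

#' OTU coverage of an abundance vector
#'
#' `1 - n1 / St`, where `St` is the number of OTUs: the estimated
#' probability that a newly formed OTU matches an existing one. An
#' extension of Good's coverage from the sequence to the OTU level; always
#' at most Good's coverage since `St <= Nt`.
#'
#' @inheritParams goods_coverage
#' @return Fraction in `[0, 1]`.
#' @export
otu_coverage <- function(ab) {
  check_abundances(ab)
  1 - sum(ab == 1) / length(ab)
}

check_abundances <- function(ab) {
  if (length(ab) == 0L) stop("empty abundance vector", call. = FALSE)
  if (any(is.na(ab)) || any(ab < 1) || any(ab != floor(ab))) {
    stop("abundances must be positive integers", call. = FALSE)
  }
  invisible(ab)
}

#' Full coverage summary
#'
#' @inheritParams goods_coverage
#' @return A list: `n_sequences`, `n_otus`, `n_singletons`,
#'   `goods_coverage`, `otu_coverage`.
#' @export
coverage_result <- function(ab) {
  check_abundances(ab)
  n1 <- sum(ab == 1)
  list(
    n_sequences = as.integer(sum(ab)),
    n_otus = length(ab),
    n_singletons = as.integer(n1),
    goods_coverage = 1 - n1 / sum(ab),
    otu_coverage = 1 - n1 / length(ab)
  )
}

#' Expected rarefied richness
#'
#' The expected number of distinct OTUs in a random subsample of `n`
#' sequences drawn without replacement (hypergeometric expectation):
#' `E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`. Binomial coefficients
#' are evaluated on the log scale, so totals beyond 10^6 sequences are
#' handled without overflow. Deterministic; see [rarefy_resample()] for a
#' Monte-Carlo cross-check.
#'
#' @inheritParams goods_coverage
#' @param n Subsample size(s), each between 1 and `sum(ab)`.
#' @return Numeric vector of expected richness values, parallel to `n`.
#' @export
rarefaction_expected <- function(ab, n) {
  check_abundances(ab)
  N <- sum(ab)
  n <- as.numeric(n)
  if (any(is.na(n)) || any(n < 1) || any(n > N) || any(n != floor(n))) {
    stop("subsample size must be an integer in [1, ", N, "]", call. = FALSE)
  }
  vapply(n, function(k) {
    # log C(N - N_i, k) - log C(N, k); lchoose returns -Inf when N - N_i < k
    lp <- lchoose(N - ab, k) - lchoose(N, k)
    sum(1 - exp(lp))
  }, numeric(1))
}

#' Rarefaction curve
#'
#' Evaluates [rarefaction_expected()] at `n = 1, 1 + step, ...` up to the
#' total number of sequences (always included as the final point, where
#' the curve equals the observed richness exactly).
#'
#' @inheritParams goods_coverage
#' @param step Spacing between consecutive subsample sizes.
#' @return A data frame with columns `n` and `richness`, carrying
#'   attributes `total_n` and `total_s`.
#' @export
rarefaction_curve <- function(ab, step = 1L) {
  check_abundances(ab)
  stopifnot(step >= 1L)
  N <- sum(ab)
  n <- unique(c(seq(1L, N, by = step), N))
  out <- data.frame(n = n, richness = rarefaction_expected(ab, n))
  attr(out, "total_n") <- as.integer(N)
  attr(out, "total_s") <- length(ab)
  out
}

#' Monte-Carlo rarefaction (cross-check mode)
#'
#' Mean observed richness over `reps` random subsamples without
#' replacement. Exists to cross-check the analytical expectation; the
#' analytical form is what reports use.
#'
#' @inheritParams rarefaction_expected
#' @param reps Number of random subsamples.
#' @return List with `mean` and `se` (standard error of the mean),
#'   parallel to `n`.
#' @export
rarefy_resample <- function(ab, n, reps = 1000L) {
  check_abundances(ab)
  N <- sum(ab)
  pool <- rep(seq_along(ab), ab)
  res <- lapply(as.integer(n), function(k) {
    rich <- vapply(seq_len(reps), function(.) {
      length(unique(pool[sample.int(N, k)]))
    }, numeric(1))
    c(mean = mean(rich), se = stats::sd(rich) / sqrt(reps))
  })
  m <- do.call(rbind, res)
  list(mean = m[, "mean"], se = m[, "se"])
}
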