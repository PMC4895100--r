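#' Specify a synthetic community
#'
#' Describes a community of true OTU "centers" plus the metadata processes
#' the census analyses consume, with every parameter of the generative
#' model explicit so each pipeline stage can be tested against known
#' ground truth:
#'
#' * a skewed abundance distribution over `s_true` centers;
#' * per-read divergence from the center capped at `within_divergence`
#'   (substitutions only, so divergence is controlled exactly), with
#'   centers kept at least `min_center_divergence` apart -- the
#'   constraint `within_divergence < min_center_divergence / 2` makes the
#'   true partition recoverable by clustering;
#' * deposition years with exponential growth until a plateau;
#' * heavily skewed submission sizes (Dirichlet weights with
#'   concentration below 1) within each year;
#' * habitat categories, optionally with phylum-level signatures;
#' * a per-phylum cultured probability and recovery-method mix;
#' * an optional per-phylum multiplier on post-pivot deposition odds, so
#'   rate-ratio analyses have a programmed enrichment to recover.
#'
#' @param s_true Number of true OTU centers.
#' @param n_seqs Total sequences sampled from the community.
#' @param alignment_length Alignment columns (including shared gap
#'   columns).
#' @param gap_fraction Fraction of columns that are gaps in every
#'   sequence (exercises both-gap handling downstream).
#' @param abundance_model `list(kind = "lognormal", meanlog =, sdlog =)`,
#'   `list(kind = "geometric", p =)`, or `list(kind = "uniform")`.
#' @param within_divergence Maximum per-read divergence from its center.
#' @param min_center_divergence Minimum pairwise center distance.
#' @param year_model `list(start_year =, growth_rate =, plateau_year =,
#'   end_year =)`; year weights grow as `exp(growth_rate * (year -
#'   start_year))` until `plateau_year`, constant thereafter.
#' @param n_submissions Submissions available per deposition year.
#' @param concentration Dirichlet concentration for submission sizes
#'   (below 1 gives the few-large-submissions skew).
#' @param environments Data frame `coarse`, `fine`, `weight` (rows from
#'   [environment_hierarchy()], `NoSource` excluded).
#' @param p_nosource Probability a record lacks an isolation source.
#' @param phylum_probs Named probabilities of each phylum (assigned per
#'   center).
#' @param phylum_year_boost Named multipliers on post-`boost_cutoff`
#'   deposition odds per phylum (default 1 for all).
#' @param boost_cutoff Pivot year for `phylum_year_boost`.
#' @param cultured_prob Named per-phylum probability that a read comes
#'   from a cultured organism.
#' @param method_probs Named probabilities over recovery methods.
#' @param seed RNG seed; the same spec always generates the same
#'   community.
#' @return A `community_spec`.
#' @export
community_spec <- function(s_true = 25L,
                           n_seqs = 150L,
                           alignment_length = 140L,
                           gap_fraction = 0.1,
                           abundance_model = list(kind = "lognormal",
                                                  meanlog = 0, sdlog = 1),
                           within_divergence = 0.01,
                           min_center_divergence = 0.08,
                           year_model = list(start_year = 1990L,
                                             growth_rate = 0.25,
                                             plateau_year = 2009L,
                                             end_year = 2015L),
                           n_submissions = 8L,
                           concentration = 0.3,
                           environments = default_environments(),
                           p_nosource = 0.05,
                           phylum_probs = c(Proteobacteria = 0.4,
                                            Firmicutes = 0.3,
                                            Actinobacteria = 0.2,
                                            Bacteroidetes = 0.1),
                           phylum_year_boost = NULL,
                           boost_cutoff = 2006L,
                           cultured_prob = c(Proteobacteria = 0.3,
                                             Firmicutes = 0.4,
                                             Actinobacteria = 0.2,
                                             Bacteroidetes = 0.05),
                           method_probs = c(traditional = 1),
                           seed = 1L) {
  stopifnot(s_true >= 1L, n_seqs >= 1L, alignment_length >= 10L,
            gap_fraction >= 0, gap_fraction < 0.5,
            within_divergence >= 0, within_divergence <= 1,
            min_center_divergence > 0, min_center_divergence <= 1)
  if (within_divergence >= min_center_divergence / 2) {
    stop("within_divergence must be below min_center_divergence / 2 ",
         "(otherwise the true partition is not recoverable)", call. = FALSE)
  }
  stopifnot(abundance_model$kind %in% c("lognormal", "geometric", "uniform"))
  stopifnot(is.data.frame(environments),
            all(c("coarse", "fine", "weight") %in% names(environments)),
            all(environments$weight >= 0), sum(environments$weight) > 0)
  check_probs <- function(p, what) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
      stop(what, " must be probabilities in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(abs(sum(phylum_probs) - 1) < 1e-8)
  check_probs(phylum_probs, "phylum_probs")
  check_probs(cultured_prob, "cultured_prob")
  if (!all(names(phylum_probs) %in% names(cultured_prob))) {
    stop("cultured_prob must cover every phylum", call. = FALSE)
  }
  stopifnot(all(names(method_probs) %in% METHOD_LEVELS),
            abs(sum(method_probs) - 1) < 1e-8)
  boost <- stats::setNames(rep(1, length(phylum_probs)),
                           names(phylum_probs))
  if (!is.null(phylum_year_boost)) {
    stopifnot(all(names(phylum_year_boost) %in% names(phylum_probs)),
              all(phylum_year_boost > 0))
    boost[names(phylum_year_boost)] <- phylum_year_boost
  }
  stopifnot(year_model$start_year <= year_model$plateau_year,
            year_model$plateau_year <= year_model$end_year,
            n_submissions >= 1L, concentration > 0,
            p_nosource >= 0, p_nosource < 1)
  structure(
    list(s_true = as.integer(s_true), n_seqs = as.integer(n_seqs),
         alignment_length = as.integer(alignment_length),
         gap_fraction = gap_fraction, abundance_model = abundance_model,
         within_divergence = within_divergence,
         min_center_divergence = min_center_divergence,
         year_model = year_model,
         n_submissions = as.integer(n_submissions),
         concentration = concentration, environments = environments,
         p_nosource = p_nosource, phylum_probs = phylum_probs,
         phylum_year_boost = boost, boost_cutoff = as.integer(boost_cutoff),
         cultured_prob = cultured_prob, method_probs = method_probs,
         seed = as.integer(seed)),
    class = "community_spec"
  )
}

#' Default habitat weights for synthetic communities
#'
#' A handful of categories with unequal weights, echoing the real
#' census's dominance of host-associated and aquatic habitats.
#'
#' @return Data frame `coarse`, `fine`, `weight`.
#' @export
default_environments <- function() {
  data.frame(
    coarse = c("Host-associated", "Aquatic", "Built", "Soil"),
    fine = c("Vertebrate", "Marine", "Digesters", "Other"),
    weight = c(0.5, 0.25, 0.15, 0.1),
    stringsAsFactors = FALSE
  )
}

# Evaluate code under a seed without disturbing the caller's RNG stream.
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate the true OTU centers of a community
#'
#' Draws `s_true` random gapped sequences over a shared column layout
#' (a fixed set of all-gap columns, random A/C/G/T elsewhere) and
#' rejection-samples until all pairwise distances are at least
#' `min_center_divergence`. Deterministic under the spec's seed.
#'
#' @param spec A [community_spec()].
#' @param max_rounds Rejection-sampling rounds before giving up.
#' @return An [aligned_seqs] collection of centers (ids `C001`, ...).
#' @export
generate_centers <- function(spec, max_rounds = 200L) {
  stopifnot(inherits(spec, "community_spec"))
  with_rng_seed(spec$seed, {
    L <- spec$alignment_length
    n_gap <- as.integer(round(spec$gap_fraction * L))
    gap_cols <- if (n_gap > 0L) sort(sample.int(L, n_gap)) else integer(0)
    base_cols <- setdiff(seq_len(L), gap_cols)
    n_base <- length(base_cols)
    draw <- function(k) {
      m <- matrix("-", nrow = k, ncol = L)
      m[, base_cols] <- sample(c("A", "C", "G", "T"),
                               k * n_base, replace = TRUE)
      m
    }
    centers <- draw(spec$s_true)
    for (round in seq_len(max_rounds)) {
      ok <- center_separation_ok(centers, base_cols,
                                 spec$min_center_divergence)
      if (all(ok)) break
      if (round == max_rounds) {
        stop("could not place ", spec$s_true, " centers at separation ",
             spec$min_center_divergence, "; lower s_true or the ",
             "separation, or lengthen the alignment", call. = FALSE)
      }
      centers[!ok, ] <- draw(sum(!ok))
    }
    seqs <- apply(centers, 1L, paste, collapse = "")
    names(seqs) <- sprintf("C%03d", seq_len(spec$s_true))
    out <- aligned_seqs(seqs, "bacteria")
    attr(out, "gap_cols") <- gap_cols
    out
  })
}

# TRUE per center iff it is far enough from every earlier-indexed center;
# flags the later of each offending pair for resampling.
center_separation_ok <- function(centers, base_cols, min_d) {
  k <- nrow(centers)
  ok <- rep(TRUE, k)
  if (k < 2L) return(ok)
  n_base <- length(base_cols)
  for (i in seq_len(k - 1L)) {
    if (!ok[i]) next
    for (j in (i + 1L):k) {
      if (!ok[j]) next
      d <- sum(centers[i, base_cols] != centers[j, base_cols]) / n_base
      if (d < min_d) ok[j] <- FALSE
    }
  }
  ok
}

#' Sample a synthetic community with known ground truth
#'
#' Draws center abundances from the spec's abundance model, emits each
#' read as its center substituted at up to
#' `floor(within_divergence * ungapped_length)` positions (so per-read
#' divergence never exceeds `within_divergence`), and draws the metadata
#' fields from the year, submission, habitat, cultured and method models.
#' The true OTU of every read is recorded.
#'
#' @param spec A [community_spec()].
#' @return A list:
#'   `seqs` ([aligned_seqs], ids `S00001`, ...),
#'   `meta` (metadata data frame with `id`, `year`, `submission_id`,
#'   `isolation_source`, `strain`, `isolate`, `record_name`, `taxonomy`,
#'   `method`, plus derived `phylum`, `cultured`, and the true `coarse` /
#'   `fine` habitat),
#'   `truth` (an `otu_partition` of the true center memberships),
#'   `centers` (the center sequences),
#'   `center_of` (named character: read id -> center id),
#'   `center_phylum`, `abundance` (named per-center read counts).
#' @export
sample_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  centers <- generate_centers(spec)
  gap_cols <- attr(centers, "gap_cols")
  with_rng_seed(spec$seed + 1L, {
    s <- spec$s_true
    n <- spec$n_seqs
    probs <- abundance_probs(spec)
    counts <- as.integer(stats::rmultinom(1L, n, probs))
    center_of <- rep(seq_len(s), counts)
    center_phylum <- sample(names(spec$phylum_probs), s, replace = TRUE,
                            prob = spec$phylum_probs)
    phylum <- center_phylum[center_of]

    base_cols <- setdiff(seq_len(spec$alignment_length), gap_cols)
    kmax <- floor(spec$within_divergence * length(base_cols))
    cmat <- seq_char_matrix(centers)
    reads <- character(n)
    for (r in seq_len(n)) {
      ch <- cmat[center_of[r], ]
      if (kmax > 0L) {
        k <- sample.int(kmax + 1L, 1L) - 1L    # uniform on 0..kmax
        if (k > 0L) {
          pos <- sample(base_cols, k)
          for (p in pos) {
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          }
        }
      }
      reads[r] <- paste(ch, collapse = "")
    }
    ids <- sprintf("S%05d", seq_len(n))
    names(reads) <- ids
    seqs <- aligned_seqs(reads, "bacteria")

    year <- draw_years(spec, phylum)
    submission_id <- draw_submissions(spec, year)
    env_idx <- sample.int(nrow(spec$environments), n, replace = TRUE,
                          prob = spec$environments$weight)
    coarse <- spec$environments$coarse[env_idx]
    fine <- spec$environments$fine[env_idx]
    isolation_source <- env_pattern(coarse, fine)
    nosource <- stats::runif(n) < spec$p_nosource
    isolation_source[nosource] <- NA_character_
    coarse[nosource] <- "NoSource"
    fine[nosource] <- "NoSource"
    cultured <- stats::runif(n) < spec$cultured_prob[phylum]
    strain <- ifelse(cultured, sprintf("strain-%05d", seq_len(n)),
                     NA_character_)
    record_name <- ifelse(cultured,
                          sprintf("%sIso%05d", phylum, seq_len(n)),
                          sprintf("Unc%s%05d", phylum, seq_len(n)))
    method <- sample(names(spec$method_probs), n, replace = TRUE,
                     prob = spec$method_probs)

    meta <- data.frame(
      id = ids, year = year, submission_id = submission_id,
      isolation_source = isolation_source,
      strain = strain, isolate = NA_character_,
      record_name = record_name,
      taxonomy = paste("Bacteria", phylum, sep = ";"),
      method = method, phylum = phylum, cultured = cultured,
      coarse = coarse, fine = fine,
      stringsAsFactors = FALSE
    )
    truth <- otu_partition(ids, center_of, threshold = 0)
    ab <- counts
    names(ab) <- names(centers)
    list(seqs = seqs, meta = meta, truth = truth, centers = centers,
         center_of = stats::setNames(names(centers)[center_of], ids),
         center_phylum = stats::setNames(center_phylum, names(centers)),
         abundance = ab)
  })
}

abundance_probs <- function(spec) {
  m <- spec$abundance_model
  s <- spec$s_true
  x <- switch(m$kind,
    lognormal = stats::rlnorm(s, m$meanlog, m$sdlog),
    geometric = m$p * (1 - m$p)^(seq_len(s) - 1L),
    uniform = rep(1, s)
  )
  x / sum(x)
}

# year weights per phylum: exponential growth to a plateau, with the
# post-boost_cutoff odds multiplied by the phylum's boost factor
year_weights <- function(spec, phylum) {
  ym <- spec$year_model
  years <- seq(ym$start_year, ym$end_year)
  w <- exp(ym$growth_rate * (pmin(years, ym$plateau_year) - ym$start_year))
  f <- spec$phylum_year_boost[[phylum]]
  w[years > spec$boost_cutoff] <- w[years > spec$boost_cutoff] * f
  list(years = years, w = w / sum(w))
}

draw_years <- function(spec, phylum) {
  n <- length(phylum)
  year <- integer(n)
  for (p in unique(phylum)) {
    sel <- phylum == p
    yw <- year_weights(spec, p)
    year[sel] <- sample(yw$years, sum(sel), replace = TRUE, prob = yw$w)
  }
  year
}

draw_submissions <- function(spec, year) {
  out <- character(length(year))
  for (y in unique(year)) {
    sel <- year == y
    w <- stats::rgamma(spec$n_submissions, shape = spec$concentration)
    w <- w / sum(w)
    idx <- sample.int(spec$n_submissions, sum(sel), replace = TRUE,
                      prob = w)
    out[sel] <- sprintf("SUB%d_%02d", y, idx)
  }
  out
}

# deterministic isolation-source string per habitat category
env_pattern <- function(coarse, fine) {
  tolower(paste(coarse, fine, "sample"))
}

#' Isolation-source mapping matching a community spec
#'
#' The mapping table that classifies the generator's isolation-source
#' strings back into their true habitat categories; write it with
#' [write_env_mapping()] to exercise the file round trip.
#'
#' @param spec A [community_spec()].
#' @return Data frame `pattern`, `coarse`, `fine`.
#' @export
env_mapping_for <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  e <- spec$environments
  data.frame(pattern = env_pattern(e$coarse, e$fine),
             coarse = e$coarse, fine = e$fine, stringsAsFactors = FALSE)
}

#' Write an isolation-source mapping file
#'
#' @param mapping Data frame `pattern`, `coarse`, `fine`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_env_mapping <- function(mapping, path) {
  stopifnot(all(c("pattern", "coarse", "fine") %in% names(mapping)))
  utils::write.table(mapping[, c("pattern", "coarse", "fine")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected phylum rate ratios of a community spec
#'
#' Closed-form expectation of [phylum_rate_ratio()] under the spec's
#' generative model: with `q_p` the probability that a phylum-`p` read is
#' deposited after the pivot, the expected fold is
#' `(q_p / (1 - q_p)) * (sum_r pi_r (1 - q_r)) / (sum_r pi_r q_r)`.
#' Serves as ground truth for recovery tests.
#'
#' Phyla are assigned per center, so a sample's phylum mixture is
#' abundance-weighted and can differ from `phylum_probs`; pass the
#' realized mixture as `pi` to condition the expectation on it.
#'
#' @param spec A [community_spec()].
#' @param cutoff_year Pivot year (defaults to the spec's boost cutoff).
#' @param pi Named phylum mixture to weight the period totals by
#'   (defaults to the spec's `phylum_probs`).
#' @return Data frame `phylum`, `q_after`, `expected_fold`.
#' @export
expected_rate_ratio <- function(spec, cutoff_year = spec$boost_cutoff,
                                pi = spec$phylum_probs) {
  stopifnot(inherits(spec, "community_spec"))
  phyla <- names(spec$phylum_probs)
  q <- vapply(phyla, function(p) {
    yw <- year_weights(spec, p)
    sum(yw$w[yw$years > cutoff_year])
  }, numeric(1))
  stopifnot(all(phyla %in% names(pi)))
  pi <- pi[phyla] / sum(pi[phyla])
  denom_after <- sum(pi * q)
  denom_before <- sum(pi * (1 - q))
  fold <- (q / (1 - q)) * (denom_before / denom_after)
  data.frame(phylum = phyla, q_after = q, expected_fold = fold,
             stringsAsFactors = FALSE, row.names = NULL)
}
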