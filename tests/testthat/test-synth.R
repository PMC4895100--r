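test_that("community specs enforce recoverability and validity", {
  expect_s3_class(community_spec(), "community_spec")
  expect_error(community_spec(within_divergence = 0.05,
                              min_center_divergence = 0.08),
               "recoverable")
  expect_error(community_spec(phylum_probs = c(A = 0.5, B = 0.6)))
  expect_error(community_spec(cultured_prob = c(Proteobacteria = 1.2)))
})

test_that("centers are separated, deterministic, and share one gap layout", {
  spec <- community_spec(s_true = 20, min_center_divergence = 0.08,
                         seed = 101)
  cen <- generate_centers(spec)
  expect_length(cen, 20L)
  st <- build_distance_store(cen)
  expect_true(all(st$d >= 0.08))           # all C(20,2) pairs separated
  expect_identical(unclass(generate_centers(spec)), unclass(cen))

  gap_cols <- attr(cen, "gap_cols")
  expect_length(gap_cols, round(0.1 * spec$alignment_length))
  m <- ssucensus:::seq_char_matrix(cen)
  expect_true(all(m[, gap_cols] == "-"))
  expect_true(all(m[, -gap_cols] %in% c("A", "C", "G", "T")))

  one <- generate_centers(community_spec(s_true = 1, seed = 5))
  expect_length(one, 1L)

  # unsatisfiable separation on a short alignment fails with guidance
  expect_error(
    generate_centers(community_spec(s_true = 40, alignment_length = 10,
                                    gap_fraction = 0,
                                    within_divergence = 0.2,
                                    min_center_divergence = 0.9,
                                    seed = 1), max_rounds = 3),
    "could not place"
  )
})

test_that("zero within-OTU divergence reproduces centers exactly", {
  spec <- community_spec(s_true = 8, n_seqs = 40, within_divergence = 0,
                         seed = 102)
  com <- sample_community(spec)
  cen <- unclass(com$centers)
  truth_groups <- split(names(com$truth$assignment), com$truth$assignment)
  for (g in truth_groups) {
    expect_length(unique(unclass(com$seqs)[g]), 1L)
    expect_true(unclass(com$seqs)[[g[1]]] %in% cen)
  }
  # clustering at any threshold >= 0 recovers the truth
  parts <- average_neighbor_cluster(build_distance_store(com$seqs),
                                    c(0, 0.03))
  for (p in parts) {
    expect_equal(canonical_partition(p$assignment),
                 canonical_partition(com$truth$assignment))
  }
})

test_that("reads stay within the divergence cap and abundances track draws", {
  spec <- community_spec(seed = 103)
  com <- sample_community(spec)
  expect_identical(sample_community(spec)$meta, com$meta)  # deterministic

  # per-read divergence from its recorded center never exceeds the cap
  centers <- unclass(com$centers)
  dists <- vapply(names(com$center_of), function(id) {
    pairwise_distance(centers[[com$center_of[[id]]]],
                      unclass(com$seqs)[[id]])
  }, numeric(1))
  expect_true(all(dists <= spec$within_divergence + 1e-12))

  # bookkeeping: recorded abundances sum to n and match the truth
  truth <- com$truth$assignment
  expect_equal(sum(com$abundance), spec$n_seqs)
  expect_equal(as.integer(table(com$center_of)[names(
    com$abundance[com$abundance > 0])]),
    as.integer(com$abundance[com$abundance > 0]))
  expect_equal(length(unique(truth)), sum(com$abundance > 0))
})

test_that("generated metadata flows through curation unchanged", {
  spec <- community_spec(seed = 104, p_nosource = 0.2)
  com <- sample_community(spec)
  mapping <- env_mapping_for(spec)
  lab <- assign_environment(com$meta, mapping)
  expect_equal(lab$coarse, com$meta$coarse)
  expect_equal(lab$fine, com$meta$fine)
  expect_identical(flag_cultured(com$meta), com$meta$cultured)
  expect_equal(taxonomy_rank(com$meta$taxonomy, 2L), com$meta$phylum)

  # file round trip: FASTA + metadata + mapping dialects
  dir <- withr::local_tempdir()
  write_aligned_fasta(com$seqs, file.path(dir, "c.fasta"))
  write_metadata(com$meta, file.path(dir, "c.tsv"))
  write_env_mapping(mapping, file.path(dir, "m.tsv"))
  seqs2 <- read_aligned_fasta(file.path(dir, "c.fasta"), "bacteria")
  meta2 <- read_metadata(file.path(dir, "c.tsv"))
  map2 <- read_env_mapping(file.path(dir, "m.tsv"))
  expect_equal(unclass(seqs2), unclass(com$seqs))
  expect_equal(meta2$id, com$meta$id)
  expect_equal(meta2$phylum, com$meta$phylum)
  lab2 <- assign_environment(meta2, map2)
  expect_equal(lab2$coarse, com$meta$coarse)
})

test_that("metadata marginals match their generating parameters", {
  spec <- community_spec(
    s_true = 40, n_seqs = 10000, seed = 105,
    phylum_probs = c(Proteobacteria = 0.45, Firmicutes = 0.35,
                     Bacteroidetes = 0.2),
    cultured_prob = c(Proteobacteria = 0.3, Firmicutes = 0.5,
                      Bacteroidetes = 0.1),
    year_model = list(start_year = 1997L, growth_rate = 0,
                      plateau_year = 1997L, end_year = 2016L)
  )
  com <- sample_community(spec)
  n <- nrow(com$meta)

  # habitat proportions within 3 SE of their weights (given a source)
  has_src <- com$meta$coarse != "NoSource"
  w <- spec$environments$weight / sum(spec$environments$weight)
  for (k in seq_along(w)) {
    p_hat <- mean(com$meta$fine[has_src] == spec$environments$fine[k])
    se <- sqrt(w[k] * (1 - w[k]) / sum(has_src))
    expect_lt(abs(p_hat - w[k]), 3 * se + 1e-9)
  }
  # missing-source rate
  se0 <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(!has_src) - spec$p_nosource), 3 * se0)

  # per-phylum cultured rates (binomial error around the programmed rate)
  for (p in names(spec$cultured_prob)) {
    sel <- com$meta$phylum == p
    if (sum(sel) < 200) next
    rate <- spec$cultured_prob[[p]]
    se <- sqrt(rate * (1 - rate) / sum(sel))
    expect_lt(abs(mean(com$meta$cultured[sel]) - rate), 3 * se)
  }

  # flat year model: share of post-2006 years = 10/20
  q <- mean(com$meta$year > 2006)
  se_q <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(q - 0.5), 3 * se_q)

  # submission skew: never more ids than configured per year, and the
  # low-concentration draw concentrates mass in few submissions
  per_year <- split(com$meta$submission_id, com$meta$year)
  expect_true(all(lengths(lapply(per_year, unique)) <=
                    spec$n_submissions))
  big_year <- per_year[[which.max(lengths(per_year))]]
  top_share <- max(table(big_year)) / length(big_year)
  expect_gt(top_share, 1.5 / spec$n_submissions)
})

test_that("programmed phylum enrichment is recovered by rate ratios", {
  spec <- community_spec(
    s_true = 40, n_seqs = 10000, seed = 106,
    phylum_probs = c(Proteobacteria = 0.55, Firmicutes = 0.45),
    cultured_prob = c(Proteobacteria = 0.2, Firmicutes = 0.2),
    phylum_year_boost = c(Firmicutes = 4),
    year_model = list(start_year = 1997L, growth_rate = 0,
                      plateau_year = 1997L, end_year = 2016L)
  )
  com <- sample_community(spec)
  rr <- phylum_rate_ratio(com$meta, cutoff_year = 2006,
                          min_sequences = 1000)
  # phyla ride on centers, so condition the expectation on the realized
  # abundance-weighted phylum mixture
  pi_hat <- prop.table(table(com$meta$phylum))
  truth <- expected_rate_ratio(spec, cutoff_year = 2006, pi = pi_hat)
  for (p in truth$phylum) {
    got <- rr$fold[rr$phylum == p]
    want <- truth$expected_fold[truth$phylum == p]
    expect_lt(abs(got - want) / want, 0.15)
  }
  # the boosted phylum is enriched, the other depleted
  expect_gt(rr$fold[rr$phylum == "Firmicutes"], 1)
  expect_lt(rr$fold[rr$phylum == "Proteobacteria"], 1)
})

test_that("deep uniform sampling saturates Good's coverage", {
  spec <- community_spec(
    s_true = 6, n_seqs = 6 * 60,           # N = 60 * S_true
    abundance_model = list(kind = "uniform"),
    within_divergence = 0, seed = 107
  )
  com <- sample_community(spec)
  ab <- abundances(com$truth)
  expect_gt(goods_coverage(ab), 0.9)
})
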