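test_that("census tables tally categories and conserve sequence counts", {
  part <- make_partition(list(
    o1 = c("a", "b", "c"), o2 = c("d", "e"), o3 = "f", o4 = "g"
  ))
  meta <- make_meta(id = letters[1:7])
  labels <- data.frame(
    coarse = c("Aquatic", "Aquatic", "Aquatic", "Aquatic", "Soil",
               "Soil", "NoSource"),
    fine = c("Marine", "Marine", "Freshwater", "Freshwater", "Other",
             "Other", "NoSource"),
    stringsAsFactors = FALSE
  )
  tab <- build_census_table(part, meta, labels)
  expect_equal(tab$coarse[nrow(tab)], "Total")
  expect_equal(tab$n_sequences[nrow(tab)], 7L)

  marine <- tab[tab$fine == "Marine", ]
  # a,b in o1; c in... a,b,c are Marine/Marine/Freshwater
  expect_equal(marine$n_sequences, 2L)
  expect_equal(marine$n_otus, 1L)       # both in o1
  expect_equal(marine$goods_coverage, 1)  # no category-scoped singleton

  fresh <- tab[tab$fine == "Freshwater", ]
  # c (o1) and d (o2) are both singletons within the category
  expect_equal(fresh$n_sequences, 2L)
  expect_equal(fresh$n_otus, 2L)
  expect_equal(fresh$goods_coverage, 0)
  expect_equal(fresh$otu_coverage, 0)

  # conservation: fine rows sum to coarse aggregates, aggregates to total
  agg <- coarse_aggregate(tab)
  expect_equal(unname(agg["Aquatic"]), 4)
  expect_equal(unname(agg["Soil"]), 2)
  expect_equal(sum(agg), tab$n_sequences[nrow(tab)])

  # OTU columns count distinct OTUs touched; they may exceed the total
  expect_gte(sum(tab$n_otus[-nrow(tab)]), tab$n_otus[nrow(tab)])

  expect_error(build_census_table(part, make_meta(id = "zz"),
                                  labels[1, , drop = FALSE]),
               "missing from partition")
})

test_that("census report rounds coverages to one-decimal percents", {
  part <- make_partition(list(o1 = c("a", "b", "c"), o2 = "d"))
  meta <- make_meta(id = letters[1:4])
  labels <- data.frame(coarse = rep("Soil", 4), fine = rep("Desert", 4))
  rep_tab <- census_report(build_census_table(part, meta, labels))
  expect_equal(rep_tab$pct_seq_coverage[1], 75.0)  # 1 - 1/4
  expect_equal(rep_tab$pct_otu_coverage[1], 50.0)  # 1 - 1/2
  expect_false("goods_coverage" %in% names(rep_tab))
})

test_that("published habitat table aggregates to its printed coarse totals", {
  bact <- silva123_habitat_census("bacteria")
  agg <- coarse_aggregate(bact)
  expect_equal(unname(agg["Aquatic"]), 214085)
  expect_equal(unname(agg["Built"]), 108799)
  expect_equal(unname(agg["Host-associated"]), 804585)
  expect_equal(unname(agg["Soil"]), 74870)
  expect_equal(sum(bact$n_sequences), 1411234)

  arch <- silva123_habitat_census("archaea")
  agg_a <- coarse_aggregate(arch)
  expect_equal(unname(agg_a["Aquatic"]), 34400)
  expect_equal(unname(agg_a["Built"]), 7286)
  expect_equal(unname(agg_a["Host-associated"]), 5597)
  expect_equal(unname(agg_a["Soil"]), 2517)
  # known discrepancy in the published archaeal table: rows sum 75 short
  # of the printed total; the data ship as printed
  total_row <- silva123_habitat_census("archaea", include_total = TRUE)
  total_row <- total_row[total_row$coarse == "Total", ]
  expect_equal(total_row$n_sequences - sum(arch$n_sequences), 75)
})

test_that("deposition-year series count known years and tally unknowns", {
  meta <- make_meta(id = letters[1:4], year = c(2005L, 2005L, 2005L, NA))
  ys <- sequences_per_year(meta)
  expect_equal(ys, data.frame(year = 2005L, n = 3L), ignore_attr = TRUE)
  expect_equal(attr(ys, "n_unknown"), 1L)

  meta2 <- make_meta(id = letters[1:3], year = c(2004L, 2004L, 2006L))
  ys2 <- sequences_per_year(meta2)
  expect_equal(ys2$n[ys2$year == 2004], 2L)
  expect_equal(ys2$n[ys2$year == 2006], 1L)
})

test_that("new OTUs are dated by their earliest member", {
  part <- make_partition(list(o1 = c("a", "b"), o2 = "c", o3 = "d",
                              o4 = "e"))
  meta <- make_meta(id = letters[1:5],
                    year = c(2005L, 2001L, 1999L, 1999L, NA))
  no <- new_otus_per_year(part, meta)
  expect_equal(no$n[no$year == 2001], 1L)  # o1 discovered 2001, not 2005
  expect_equal(no$n[no$year == 1999], 2L)  # two singleton OTUs
  expect_false(2005 %in% no$year)
  expect_equal(attr(no, "n_unknown_otus"), 1L)  # o4's only member lacks a year
  # conservation: dated OTUs + unknown = all OTUs
  expect_equal(sum(no$n) + attr(no, "n_unknown_otus"),
               length(unique(part$assignment)))
})

test_that("submissions_for_half is the minimal majority set", {
  mk <- function(sizes) {
    make_meta(id = sprintf("s%03d", seq_len(sum(sizes))), year = 2010L,
              submission_id = rep(sprintf("SUB%02d", seq_along(sizes)),
                                  sizes))
  }
  expect_equal(submissions_for_half(mk(c(60, 40)), 2010), 1L)
  expect_equal(submissions_for_half(mk(c(40, 30, 30)), 2010), 2L)
  expect_equal(submissions_for_half(mk(rep(10, 10)), 2010), 5L)
  expect_error(submissions_for_half(mk(c(5, 5)), 1999), "no records")

  # minimality: the top (k - 1) submissions hold < 50%
  withr::local_seed(31)
  for (rep in 1:20) {
    sizes <- sample.int(30, sample(2:8, 1), replace = TRUE)
    meta <- mk(sizes)
    k <- submissions_for_half(meta, 2010)
    sorted <- sort(sizes, decreasing = TRUE)
    expect_gte(sum(sorted[seq_len(k)]), sum(sizes) / 2)
    if (k > 1) expect_lt(sum(sorted[seq_len(k - 1)]), sum(sizes) / 2)
  }
})

test_that("phylum rate ratios compare period shares", {
  meta <- make_meta(
    id = sprintf("s%02d", 1:12),
    year = c(rep(2000L, 6), rep(2010L, 6)),
    taxonomy = paste0("Bacteria;", c(rep("Firmicutes", 3),
                                     rep("Proteobacteria", 3),
                                     rep("Firmicutes", 3),
                                     rep("Proteobacteria", 3)))
  )
  rr <- phylum_rate_ratio(meta, cutoff_year = 2006, min_sequences = 5)
  # identical shares in both periods -> fold 1, log2 0
  expect_equal(rr$fold, c(1, 1))
  expect_equal(rr$log2_fold, c(0, 0))
  expect_true(all(rr$meets_min))

  # phylum absent before the pivot is flagged undefined
  meta2 <- rbind(meta, make_meta(id = "new", year = 2012L,
                                 taxonomy = "Bacteria;Atribacteria"))
  rr2 <- phylum_rate_ratio(meta2, cutoff_year = 2006)
  atri <- rr2[rr2$phylum == "Atribacteria", ]
  expect_true(atri$undefined)
  expect_true(is.na(atri$fold))
  expect_false(atri$meets_min)
})

test_that("cultured summaries count sequences and OTUs separately", {
  part <- make_partition(list(o1 = sprintf("s%02d", 1:10)))
  meta <- make_meta(id = sprintf("s%02d", 1:10),
                    taxonomy = "Bacteria;Firmicutes")
  meta$cultured <- c(TRUE, rep(FALSE, 9))
  cs <- cultured_summary(part, meta)
  expect_equal(cs$pct_sequences_cultured, 10)
  expect_equal(cs$pct_otus_with_cultured_rep, 100)

  meta$cultured <- rep(TRUE, 10)
  cs2 <- cultured_summary(part, meta)
  expect_equal(cs2$pct_sequences_cultured, 100)
  expect_equal(cs2$pct_otus_with_cultured_rep, 100)

  # flag_cultured route: strain field + record name rule
  meta3 <- make_meta(id = c("x", "y"), strain = c("DSM 1", NA),
                     record_name = c("Iso1", "UncBac2"),
                     taxonomy = "Bacteria;Bacteroidetes")
  part3 <- make_partition(list(o1 = "x", o2 = "y"))
  cs3 <- cultured_summary(part3, meta3)
  expect_equal(cs3$pct_sequences_cultured, 50)
  expect_equal(cs3$pct_otus_with_cultured_rep, 50)
})

test_that("method overlap percentages follow the shared-OTU definition", {
  # only one method: diagonal 100
  part1 <- make_partition(list(o1 = c("a", "b")))
  m1 <- method_overlap(part1, make_meta(id = c("a", "b")))
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(m1["traditional", "traditional"], 100)

  # two methods co-clustered in one OTU: off-diagonal 100, diagonal 0
  meta2 <- make_meta(id = c("a", "b"),
                     method = c("traditional", "single_cell"))
  m2 <- method_overlap(part1, meta2)
  expect_equal(m2["traditional", "single_cell"], 100)
  expect_equal(m2["single_cell", "traditional"], 100)
  expect_equal(m2["traditional", "traditional"], 0)

  # toy: A touches {o1, o2, o3}, B touches {o1} -> (A, B) = 33.3%
  part3 <- make_partition(list(o1 = c("a1", "b1"), o2 = "a2", o3 = "a3"))
  meta3 <- make_meta(id = c("a1", "a2", "a3", "b1"),
                     method = c(rep("traditional", 3), "emirge_pcr"))
  m3 <- method_overlap(part3, meta3)
  expect_equal(m3["traditional", "emirge_pcr"], 100 / 3)
  expect_equal(m3["emirge_pcr", "traditional"], 100)
  expect_equal(m3["traditional", "traditional"], 200 / 3)  # o2, o3 exclusive
  expect_equal(m3["emirge_pcr", "emirge_pcr"], 0)

  # relabelling methods permutes the matrix consistently
  swap <- c(traditional = "single_cell", emirge_pcr = "traditional")
  meta4 <- meta3
  meta4$method <- unname(swap[meta3$method])
  m4 <- method_overlap(part3, meta4)
  expect_equal(m4["single_cell", "traditional"],
               m3["traditional", "emirge_pcr"])
  expect_equal(m4["traditional", "single_cell"],
               m3["emirge_pcr", "traditional"])
})

test_that("figshare-format tables rebuild a partition and recompute coverage", {
  df <- data.frame(
    id = sprintf("s%02d", 1:6),
    otu = c("OTU1", "OTU1", "OTU1", "OTU2", "OTU2", "OTU3"),
    year = c(2001, 2002, 2003, 2004, 2005, 2006),
    taxonomy = paste0("Bacteria;", c(rep("Firmicutes", 4),
                                     rep("Proteobacteria", 2))),
    coarse = "Soil", fine = "Desert",
    stringsAsFactors = FALSE
  )
  path <- write_figshare_fixture(df)
  x <- read_figshare_census(path, threshold = 0.03)
  expect_equal(sort(unique(x$partition$assignment)),
               c("OTU1", "OTU2", "OTU3"))
  expect_equal(x$meta$phylum[1], "Firmicutes")
  cv <- coverage_result(abundances(x$partition))
  expect_equal(cv$n_sequences, 6L)
  expect_equal(cv$n_otus, 3L)
  expect_equal(cv$goods_coverage, 1 - 1 / 6)
  expect_equal(cv$otu_coverage, 1 - 1 / 3)

  df_bad <- df; df_bad$otu[2] <- NA
  expect_error(read_figshare_census(write_figshare_fixture(df_bad)),
               "missing OTU")
  expect_error(read_figshare_census(write_figshare_fixture(df[, "id",
                                                              drop = FALSE])),
               "'id' and 'otu'")
})
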