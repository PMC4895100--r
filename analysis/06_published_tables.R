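#!/usr/bin/env Rscript
# Arithmetic on the published census tables shipped with the package:
# aggregate the fine habitat rows to coarse totals per domain and compute
# the 2009-2012 submission-concentration share.

source("analysis/00_config.R")

rows <- lapply(c("bacteria", "archaea"), function(dom) {
  tab <- silva123_habitat_census(dom)
  agg <- coarse_aggregate(tab)
  data.frame(domain = dom, coarse = names(agg),
             n_sequences = as.integer(agg), stringsAsFactors = FALSE)
})
agg <- do.call(rbind, rows)
write_tsv(agg, file.path(RESULTS_DIR, "published_coarse_aggregates.tsv"))

bact_total <- sum(silva123_habitat_census("bacteria")$n_sequences)
arch_rows <- sum(silva123_habitat_census("archaea")$n_sequences)
arch_printed <- silva123_habitat_census("archaea", include_total = TRUE)
arch_printed <- arch_printed$n_sequences[arch_printed$coarse == "Total"]
message("bacterial fine rows sum to ", bact_total)
message("archaeal fine rows sum to ", arch_rows, " vs printed total ",
        arch_printed, " (known discrepancy of ",
        arch_printed - arch_rows, ")")

w <- silva123_deposition_window()
message(sprintf(
  "%d-%d: top %d submissions deposited %d of %d sequences (%.1f%%)",
  w$years[1], w$years[2], w$n_top_submissions, w$n_top, w$n_total,
  submission_share_pct(w$n_top, w$n_total)))
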