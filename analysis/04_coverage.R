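#!/usr/bin/env Rscript
# Coverage statistics and rarefaction: the habitat census table
# (sequences, OTUs, Good's and OTU coverage per category) and rarefaction
# curves per threshold.

source("analysis/00_config.R")

meta <- utils::read.delim(file.path(SYN_DIR, "curated_metadata.tsv"),
                          stringsAsFactors = FALSE)
parts <- read_otu_list(file.path(SYN_DIR, "otus.list"))
p03 <- parts[["0.03"]]

labels <- meta[, c("coarse", "fine")]
tab <- build_census_table(p03, meta, labels)
write_tsv(census_report(tab), file.path(RESULTS_DIR, "habitat_census.tsv"))

total <- tab[tab$coarse == "Total", ]
message(sprintf(
  "census at 3%%: %d sequences, %d OTUs, Good's coverage %.1f%%, OTU coverage %.1f%%",
  total$n_sequences, total$n_otus, 100 * total$goods_coverage,
  100 * total$otu_coverage))

curves <- do.call(rbind, lapply(parts, function(p) {
  rc <- rarefaction_curve(abundances(p), step = 10)
  cbind(threshold = p$threshold, rc)
}))
write_tsv(curves, file.path(RESULTS_DIR, "rarefaction_curves.tsv"))
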