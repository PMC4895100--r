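#!/usr/bin/env Rscript
# Temporal and taxonomic census analyses on the curated community:
# deposition per year, new OTUs per year, submission concentration,
# phylum rate ratios around 2006, the cultured census, and cross-method
# OTU overlap.

source("analysis/00_config.R")

meta <- utils::read.delim(file.path(SYN_DIR, "curated_metadata.tsv"),
                          stringsAsFactors = FALSE)
p03 <- read_otu_list(file.path(SYN_DIR, "otus.list"))[["0.03"]]

per_year <- sequences_per_year(meta)
new_otus <- new_otus_per_year(p03, meta)
trend <- merge(per_year, new_otus, by = "year", all = TRUE,
               suffixes = c("_sequences", "_new_otus"))
trend$submissions_for_half <- vapply(trend$year, function(y) {
  submissions_for_half(meta, y)
}, integer(1))
write_tsv(trend, file.path(RESULTS_DIR, "deposition_trends.tsv"))
recent <- trend[trend$year >= 2010, ]
message(sprintf(
  "since 2010: %.0f sequences/year on average; <= %d submissions held half of any year",
  mean(recent$n_sequences), max(trend$submissions_for_half)))

rr <- phylum_rate_ratio(meta, cutoff_year = 2006, min_sequences = 30)
write_tsv(rr, file.path(RESULTS_DIR, "phylum_rate_ratios.tsv"))
defined <- rr[!rr$undefined, ]
top <- defined[which.max(defined$fold), ]
message(sprintf("most enriched phylum after 2006: %s (%.1f-fold)",
                top$phylum, top$fold))

cs <- cultured_summary(p03, meta)
write_tsv(cs, file.path(RESULTS_DIR, "cultured_census.tsv"))
message(sprintf("cultured overall: %.1f%% of sequences, %.1f%% of OTUs touched",
                100 * sum(meta$cultured) / nrow(meta),
                mean(cs$pct_otus_with_cultured_rep)))

ov <- method_overlap(p03, meta)
write_tsv(cbind(method = rownames(ov), as.data.frame(ov)),
          file.path(RESULTS_DIR, "method_overlap.tsv"))
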