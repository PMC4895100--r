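# Shared configuration for the analysis workflow.
#
# The study community: richer than the package default so every census
# analysis downstream has signal -- a skewed lognormal abundance profile,
# four phyla with one programmed post-2006 enrichment, a mix of recovery
# methods, and a small missing-source fraction.

library(ssucensus)

RESULTS_DIR <- "results"
SYN_DIR <- file.path(RESULTS_DIR, "synthetic")
THRESHOLDS <- c(0, 0.03, 0.05, 0.10, 0.20)

study_spec <- function(seed = 2016L) {
  community_spec(
    s_true = 40,
    n_seqs = 300,
    alignment_length = 160,
    within_divergence = 0.01,
    min_center_divergence = 0.08,
    phylum_probs = c(Proteobacteria = 0.40, Firmicutes = 0.30,
                     Actinobacteria = 0.20, Bacteroidetes = 0.10),
    phylum_year_boost = c(Bacteroidetes = 4),
    cultured_prob = c(Proteobacteria = 0.30, Firmicutes = 0.40,
                      Actinobacteria = 0.20, Bacteroidetes = 0.05),
    method_probs = c(traditional = 0.90, single_cell = 0.05,
                     emirge_pcr = 0.05),
    p_nosource = 0.08,
    seed = seed
  )
}

write_tsv <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  message("wrote ", path)
}
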