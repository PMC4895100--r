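#!/usr/bin/env Rscript
# Simulate the study community and write it in the pipeline's file
# dialects (gapped FASTA, metadata TSV, isolation-source mapping), plus
# the ground truth the later steps are judged against.

source("analysis/00_config.R")

spec <- study_spec()
com <- sample_community(spec)

dir.create(SYN_DIR, recursive = TRUE, showWarnings = FALSE)
write_aligned_fasta(com$seqs, file.path(SYN_DIR, "community.fasta"))
write_metadata(com$meta, file.path(SYN_DIR, "metadata.tsv"))
write_env_mapping(env_mapping_for(spec), file.path(SYN_DIR, "mapping.tsv"))
write_otu_list(com$truth, file.path(SYN_DIR, "truth.list"))

message(sprintf(
  "simulated %d sequences from %d centers (%d sampled), %d phyla, %d habitats",
  length(com$seqs), spec$s_true, sum(com$abundance > 0),
  length(unique(com$meta$phylum)),
  length(unique(com$meta$fine[com$meta$fine != "NoSource"]))
))
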