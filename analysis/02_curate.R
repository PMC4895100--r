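#!/usr/bin/env Rscript
# Curate the simulated export the way the census curates the database
# export: screen ambiguous base calls, trim to a shared overlap window,
# classify habitats from isolation-source strings, flag cultured records.

source("analysis/00_config.R")

seqs <- read_aligned_fasta(file.path(SYN_DIR, "community.fasta"),
                           "bacteria")
meta <- read_metadata(file.path(SYN_DIR, "metadata.tsv"))
mapping <- read_env_mapping(file.path(SYN_DIR, "mapping.tsv"))

screened <- screen_sequences(seqs, max_ambiguous = 2)
message(length(seqs), " sequences read; ", attr(screened, "n_removed"),
        " removed by the >2-ambiguity screen")

# overlap window stated in unaligned positions of the first record and
# converted to alignment columns, as for a published reference window
ref <- unclass(screened)[[1L]]
n_unaligned <- nchar(gsub("[-.]", "", ref))
cols <- ref_positions_to_columns(ref, c(3L, n_unaligned - 2L))
trimmed <- trim_to_overlap(screened, cols[1], cols[2])
message("trimmed to columns ", cols[1], "-", cols[2], "; ",
        attr(trimmed, "n_discarded"), " sequences did not span the window")

meta <- meta[match(names(trimmed), meta$id), ]
labels <- assign_environment(meta, mapping)
meta$coarse <- labels$coarse
meta$fine <- labels$fine
meta$cultured <- flag_cultured(meta)

write_aligned_fasta(trimmed, file.path(SYN_DIR, "curated.fasta"))
write_tsv(meta, file.path(SYN_DIR, "curated_metadata.tsv"))
message(nrow(meta), " curated sequences; ",
        sum(meta$coarse == "NoSource"), " without isolation source; ",
        sum(meta$cultured), " from cultured organisms")
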