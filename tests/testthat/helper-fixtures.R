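# Small in-code fixtures shared across test files.

make_meta <- function(id,
                      year = NA_integer_,
                      submission_id = NA_character_,
                      isolation_source = NA_character_,
                      strain = NA_character_,
                      isolate = NA_character_,
                      record_name = "Rec",
                      taxonomy = "Bacteria;Proteobacteria",
                      method = "traditional") {
  df <- data.frame(
    id = id, year = year, submission_id = submission_id,
    isolation_source = isolation_source, strain = strain,
    isolate = isolate, record_name = record_name, taxonomy = taxonomy,
    method = method, stringsAsFactors = FALSE
  )
  df$phylum <- taxonomy_rank(df$taxonomy, 2L)
  df
}

# A fixed partition over explicit groups, e.g. list(o1 = c("a","b")).
make_partition <- function(groups, threshold = 0.03) {
  assignment <- rep(names(groups), lengths(groups))
  names(assignment) <- unlist(groups)
  structure(list(threshold = threshold, assignment = assignment,
                 heights = numeric(0)),
            class = "otu_partition")
}

# Write a figshare-shaped per-sequence census table and return its path.
write_figshare_fixture <- function(df, dir = withr::local_tempdir(
                                     .local_envir = parent.frame())) {
  path <- file.path(dir, "figshare_census.tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

small_mapping <- function() {
  data.frame(
    pattern = c("seawater", "human gut", "forest soil"),
    coarse = c("Aquatic", "Host-associated", "Soil"),
    fine = c("Marine", "Vertebrate", "Other"),
    stringsAsFactors = FALSE
  )
}
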