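Package: ssucensus
Title: Census Statistics for Full-Length SSU rRNA Gene Sequence Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for taking stock of a molecular census of bacteria and
    archaea built from aligned full-length 16S rRNA gene sequences. The
    package curates aligned sequence collections and their metadata
    (ambiguous-base screening, trimming to a shared alignment window,
    habitat classification, cultured-organism flagging), computes pairwise
    uncorrected distances with explicit gap-run handling, clusters sequences
    into operational taxonomic units (OTUs) by average-neighbor (average
    linkage) agglomeration at multiple distance thresholds, and derives
    census statistics: Good's coverage, singleton-based OTU coverage,
    analytical rarefaction, habitat census tables, deposition-year trends,
    submission concentration, phylum deposition-rate ratios, cultured
    fractions, and cross-method OTU overlap. A synthetic-community
    generator with known ground truth makes every stage testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
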