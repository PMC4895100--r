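#' Screen sequences by ambiguous base calls
#'
#' Removes sequences with more than `max_ambiguous` ambiguity characters.
#' Any character other than A, C, G, T, U (case-insensitive) or a gap
#' (`-`, `.`) counts as an ambiguous base call, so N and the other IUPAC
#' codes are all counted.
#'
#' @param seqs An [aligned_seqs] collection.
#' @param max_ambiguous Maximum number of ambiguous calls retained
#'   (default 2, i.e. sequences with more than two ambiguous base calls
#'   are removed).
#' @return The filtered collection, with attribute `n_removed` giving the
#'   number of sequences discarded.
#' @export
screen_sequences <- function(seqs, max_ambiguous = 2L) {
  stopifnot(inherits(seqs, "aligned_seqs"), max_ambiguous >= 0L)
  if (length(seqs) == 0L) {
    out <- seqs
    attr(out, "n_removed") <- 0L
    return(out)
  }
  allowed <- c(CANONICAL_BASES, GAP_CHARS)
  n_ambig <- vapply(
    strsplit(toupper(unclass(seqs)), "", fixed = TRUE),
    function(ch) sum(!ch %in% allowed),
    integer(1)
  )
  keep <- n_ambig <= max_ambiguous
  out <- seqs[keep]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Trim sequences to a shared alignment window
#'
#' Slices every sequence to alignment columns `[start, end]` (1-based,
#' inclusive), keeping only sequences whose sequenced region spans the
#' whole window, so every retained sequence fully overlaps the common
#' region. Coverage follows the alignment convention of the source
#' databases: `.` marks missing data (the unsequenced terminal stretch),
#' while `-` marks a deletion *within* the sequenced region and therefore
#' counts as coverage. A sequence spans the window when its first and last
#' non-`.` characters lie at or outside the window bounds; slices that
#' contain no bases at all are discarded as well. Under this convention
#' trimming is idempotent: re-trimming a trimmed collection over its full
#' width changes nothing.
#'
#' Published windows stated as unaligned reference positions can be
#' converted to columns with [ref_positions_to_columns()].
#'
#' @param seqs An [aligned_seqs] collection.
#' @param start,end Alignment columns bounding the window.
#' @return The trimmed collection, with attribute `n_discarded` counting
#'   sequences that did not span the window.
#' @export
trim_to_overlap <- function(seqs, start, end) {
  stopifnot(inherits(seqs, "aligned_seqs"))
  start <- as.integer(start); end <- as.integer(end)
  if (length(seqs) == 0L) {
    out <- seqs
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  len <- nchar(seqs[[1L]])
  if (is.na(start) || is.na(end) || start < 1L || end > len || start > end) {
    stop("window [", start, ", ", end, "] outside alignment of length ", len,
         call. = FALSE)
  }
  x <- unclass(seqs)
  first_cov <- regexpr("[^.]", x)
  last_cov <- len - as.integer(regexpr("[^.]",
    vapply(x, function(s)
      paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""),
      character(1), USE.NAMES = FALSE))) + 1L
  slice <- substr(x, start, end)
  has_base <- grepl("[^-.]", slice)
  spans <- first_cov > 0L & first_cov <= start & last_cov >= end & has_base
  out <- aligned_seqs(slice[spans], attr(seqs, "domain_tag"))
  attr(out, "n_discarded") <- sum(!spans)
  out
}

#' The fixed habitat-category hierarchy
#'
#' Environmental origins are classified on two levels: seven broad coarse
#' categories (plus `NoSource` for records without an isolation source) and
#' the fine categories nested under them. The hierarchy is fixed; mapping
#' files and census tables are validated against it.
#'
#' @return A data frame with columns `coarse` and `fine`, one row per fine
#'   category (including the degenerate Aerosol, Other and NoSource rows).
#' @export
environment_hierarchy <- function() {
  h <- list(
    Aerosol = "Aerosol",
    Aquatic = c("Brackish", "Brackish sediment", "Freshwater",
                "Freshwater sediment", "Marine", "Marine sediment",
                "Hydrothermal vent", "Ice", "Other"),
    Built = c("Digesters", "Food-associated", "Industrial/mining",
              "Pollution-associated", "Other"),
    `Plant-associated` = c("Root", "Surface", "Other"),
    Soil = c("Agriculture", "Desert", "Permafrost", "Other"),
    `Host-associated` = c("Vertebrate", "Arthropod", "Other invertebrate",
                          "Other"),
    Other = "Other",
    NoSource = "NoSource"
  )
  data.frame(
    coarse = rep(names(h), lengths(h)),
    fine = unlist(h, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

normalize_source <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

#' Read an isolation-source mapping file
#'
#' The mapping externalizes the manual judgment of habitat classification:
#' a tab-separated file with header `pattern`, `coarse`, `fine`, one row per
#' isolation-source string. Patterns are matched case-insensitively after
#' whitespace normalization; coarse/fine pairs must belong to the fixed
#' hierarchy ([environment_hierarchy()]).
#'
#' @param path Path to the mapping file.
#' @return A data frame with columns `pattern`, `coarse`, `fine`.
#' @export
read_env_mapping <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty mapping file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1L]])
  if (!identical(header, c("pattern", "coarse", "fine"))) {
    stop("mapping line 1: expected header 'pattern<TAB>coarse<TAB>fine'",
         call. = FALSE)
  }
  hier <- environment_hierarchy()
  hier_key <- paste(hier$coarse, hier$fine, sep = "\r")
  rows <- vector("list", length(fields) - 1L)
  for (i in seq_along(rows)) {
    f <- fields[[i + 1L]]
    lineno <- i + 1L
    if (length(f) != 3L) {
      stop("mapping line ", lineno, ": expected 3 tab-separated fields, got ",
           length(f), call. = FALSE)
    }
    f <- trimws(f)
    if (!nzchar(f[1L])) {
      stop("mapping line ", lineno, ": empty pattern", call. = FALSE)
    }
    if (!paste(f[2L], f[3L], sep = "\r") %in% hier_key) {
      stop("mapping line ", lineno, ": '", f[2L], "' / '", f[3L],
           "' is not a coarse/fine pair of the habitat hierarchy",
           call. = FALSE)
    }
    rows[[i]] <- f
  }
  m <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(m) <- c("pattern", "coarse", "fine")
  norm <- normalize_source(m$pattern)
  if (anyDuplicated(norm)) {
    dup <- m$pattern[duplicated(norm)][1L]
    stop("duplicate pattern after normalization: '", dup, "'", call. = FALSE)
  }
  m
}

#' Assign habitat categories from isolation-source strings
#'
#' Looks each record's `isolation_source` up in a mapping table
#' (see [read_env_mapping()]); matching is exact after lower-casing and
#' whitespace normalization. Records with no isolation source collected get
#' `NoSource`; records whose source is present but unmapped fall into the
#' coarse `Other` category. The two are reported separately in census
#' tables.
#'
#' @param meta A metadata data frame with an `isolation_source` column
#'   (`NA` or `""` meaning not collected).
#' @param mapping A mapping data frame from [read_env_mapping()].
#' @return A data frame with columns `coarse` and `fine`, one row per
#'   record of `meta`, in input order.
#' @export
assign_environment <- function(meta, mapping) {
  stopifnot(is.data.frame(meta), "isolation_source" %in% names(meta),
            is.data.frame(mapping),
            all(c("pattern", "coarse", "fine") %in% names(mapping)))
  src <- meta$isolation_source
  missing <- is.na(src) | !nzchar(trimws(src))
  idx <- match(normalize_source(src), normalize_source(mapping$pattern))
  coarse <- mapping$coarse[idx]
  fine <- mapping$fine[idx]
  unmapped <- !missing & is.na(idx)
  coarse[unmapped] <- "Other"
  fine[unmapped] <- "Other"
  coarse[missing] <- "NoSource"
  fine[missing] <- "NoSource"
  data.frame(coarse = coarse, fine = fine, stringsAsFactors = FALSE)
}

#' Flag sequences from cultured organisms
#'
#' A record is taken to come from a cultured organism when its `strain` or
#' `isolate` field carries data and its database record name does not
#' contain the substring `"Unc"` (the database convention marking
#' sequences from uncultured organisms; matched case-sensitively).
#'
#' @param meta A metadata data frame with columns `strain`, `isolate`,
#'   `record_name`.
#' @return Logical vector, one element per record.
#' @export
flag_cultured <- function(meta) {
  stopifnot(is.data.frame(meta),
            all(c("strain", "isolate", "record_name") %in% names(meta)))
  has <- function(x) !is.na(x) & nzchar(trimws(x))
  unc <- !is.na(meta$record_name) &
    grepl("Unc", meta$record_name, fixed = TRUE)
  (has(meta$strain) | has(meta$isolate)) & !unc
}

METHOD_LEVELS <- c("traditional", "single_cell", "emirge_pcr",
                   "emirge_metagenomic")

#' Read a per-sequence metadata table
#'
#' Tab-separated with header columns `id`, `year`, `submission_id`,
#' `isolation_source`, `strain`, `isolate`, `record_name`, `taxonomy`,
#' `method`. `taxonomy` is a semicolon-joined rank string starting at the
#' domain (e.g. `"Bacteria;Firmicutes;..."`). Missing `method` defaults to
#' `"traditional"`.
#'
#' @param path Path to the metadata file.
#' @return A data frame with the columns above plus derived `phylum`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character", na.strings = c("NA", ""))
  required <- c("id", "year", "submission_id", "isolation_source", "strain",
                "isolate", "record_name", "taxonomy", "method")
  miss <- setdiff(required, names(meta))
  if (length(miss) > 0L) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$id)) {
    stop("duplicate metadata id(s): ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "),
         call. = FALSE)
  }
  meta$year <- as.integer(meta$year)
  meta$method[is.na(meta$method)] <- "traditional"
  bad <- setdiff(unique(meta$method), METHOD_LEVELS)
  if (length(bad) > 0L) {
    stop("unknown recovery method(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  meta$phylum <- taxonomy_rank(meta$taxonomy, 2L)
  meta
}

#' Write a per-sequence metadata table
#'
#' @param meta Metadata data frame (see [read_metadata()] for columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  cols <- c("id", "year", "submission_id", "isolation_source", "strain",
            "isolate", "record_name", "taxonomy", "method")
  utils::write.table(meta[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Extract a rank from semicolon-joined taxonomy strings
#'
#' @param taxonomy Character vector of `;`-joined rank names
#'   (domain first).
#' @param rank 1-based rank index (1 = domain, 2 = phylum).
#' @return Character vector (`NA` where the rank is absent).
#' @export
taxonomy_rank <- function(taxonomy, rank = 2L) {
  parts <- strsplit(as.character(taxonomy), ";", fixed = TRUE)
  vapply(parts, function(p) {
    p <- trimws(p)
    if (length(p) >= rank && nzchar(p[rank])) p[rank] else NA_character_
  }, character(1))
}
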