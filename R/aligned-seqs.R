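#' Aligned sequence collection
#'
#' An `aligned_seqs` object is a named character vector of gapped sequences
#' sharing one alignment coordinate system: every sequence has the same
#' gapped length, names (accessions) are unique, and both `-` and `.` are
#' accepted as gap characters. A `domain_tag` attribute records whether the
#' collection is bacterial or archaeal.
#'
#' @param x Named character vector of gapped sequences.
#' @param domain_tag `"bacteria"` or `"archaea"`.
#' @return An `aligned_seqs` object.
#' @examples
#' aligned_seqs(c(s1 = "ACGT-", s2 = "AC.TT"), "bacteria")
#' @export
aligned_seqs <- function(x, domain_tag = c("bacteria", "archaea")) {
  domain_tag <- match.arg(domain_tag)
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  if (length(x) > 0L) {
    ids <- names(x)
    if (is.null(ids) || any(!nzchar(ids))) {
      stop("every sequence must be named by its accession", call. = FALSE)
    }
    if (anyDuplicated(ids)) {
      dup <- unique(ids[duplicated(ids)])
      stop("duplicate sequence id(s): ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
    if (any(!nzchar(x))) {
      stop("empty residue string for id(s): ",
           paste(ids[!nzchar(x)], collapse = ", "), call. = FALSE)
    }
    len <- nchar(x)
    if (length(unique(len)) > 1L) {
      ref <- len[1L]
      bad <- ids[len != ref][1L]
      stop("unequal gapped lengths: '", bad, "' has length ",
           nchar(x[[bad]]), ", expected ", ref, call. = FALSE)
    }
  }
  structure(x, class = "aligned_seqs", domain_tag = domain_tag)
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat("<aligned_seqs> ", length(x), " ", attr(x, "domain_tag"),
      " sequence(s)", sep = "")
  if (length(x) > 0L) cat(", alignment length ", nchar(x[[1L]]), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
`[.aligned_seqs` <- function(x, i, ...) {
  aligned_seqs(unclass(x)[i], attr(x, "domain_tag"))
}

GAP_CHARS <- c("-", ".")
CANONICAL_BASES <- c("A", "C", "G", "T", "U")

#' Read an aligned FASTA file
#'
#' Reads a gapped FASTA alignment (wrapped lines allowed; `-` and `.` both
#' treated as gaps) and validates that all records share one gapped length
#' and that ids are unique. The id is the first whitespace-delimited token
#' of each header.
#'
#' @param path Path to a FASTA file.
#' @param domain_tag `"bacteria"` or `"archaea"`.
#' @return An [aligned_seqs] collection (empty file gives an empty one).
#' @export
read_aligned_fasta <- function(path, domain_tag = c("bacteria", "archaea")) {
  domain_tag <- match.arg(domain_tag)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) {
    return(aligned_seqs(character(0), domain_tag))
  }
  ss <- Biostrings::readBStringSet(path)
  x <- as.character(ss)
  names(x) <- sub("\\s.*$", "", names(ss))
  aligned_seqs(x, domain_tag)
}

#' Write an aligned FASTA file
#'
#' @param seqs An [aligned_seqs] collection.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Convert unaligned reference positions to alignment columns
#'
#' Published trimming windows are usually stated as unaligned positions of a
#' reference sequence (e.g. *E. coli* 113--1350 or *S. solfataricus*
#' 362--937). This helper maps such positions to 1-based columns of the
#' shared alignment, given the gapped reference sequence.
#'
#' @param reference A single gapped sequence (character scalar) in the
#'   collection's coordinate system.
#' @param positions Integer vector of 1-based unaligned positions.
#' @return Integer vector of alignment columns, one per position.
#' @export
ref_positions_to_columns <- function(reference, positions) {
  stopifnot(is.character(reference), length(reference) == 1L)
  chars <- strsplit(reference, "", fixed = TRUE)[[1L]]
  nongap <- which(!chars %in% GAP_CHARS)
  positions <- as.integer(positions)
  if (any(positions < 1L | positions > length(nongap))) {
    stop("reference has only ", length(nongap), " unaligned positions",
         call. = FALSE)
  }
  nongap[positions]
}

# Character matrix view (rows = sequences) used by distance and trimming code.
seq_char_matrix <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = 0L))
  }
  m <- do.call(rbind, strsplit(toupper(unclass(seqs)), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  m
}
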