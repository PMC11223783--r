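#' Reference sequence for a single mitochondrial contig
#'
#' A `mito_reference` is a plain list with fields `name` (contig identifier),
#' `sequence` (uppercase string over A/C/G/T/N) and `length` (bp). The
#' toolkit deliberately supports a single contig: reads aligned to anything
#' else are a QC failure, not an input mode.
#'
#' @param name Contig identifier (non-empty string).
#' @param sequence Sequence string; lowercase is accepted and uppercased.
#' @return An object of class `mito_reference`.
#' @examples
#' ref <- mito_reference("chrM", "acgt")
#' ref$length
#' @export
mito_reference <- function(name, sequence) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("reference sequence is empty")
  }
  if (grepl("[^ACGTN]", sequence)) {
    stop("reference sequence contains characters outside {A,C,G,T,N}")
  }
  structure(
    list(name = name, sequence = sequence, length = nchar(sequence)),
    class = "mito_reference"
  )
}

#' @export
print.mito_reference <- function(x, ...) {
  cat(sprintf(
    "<mito_reference> %s: %d bp (%s...)\n",
    x$name, x$length, substr(x$sequence, 1L, min(12L, x$length))
  ))
  invisible(x)
}

#' Extract reference bases by position
#'
#' @param reference A [mito_reference()].
#' @param pos 1-based start position(s).
#' @param len Length of the slice taken at each `pos` (recycled).
#' @return Character vector of subsequences.
#' @keywords internal
ref_bases <- function(reference, pos, len = 1L) {
  substring(reference$sequence, pos, pos + len - 1L)
}

#' Read a single-record FASTA reference
#'
#' Multi-record FASTA files are rejected: the toolkit models one
#' mitochondrial contig. The name is the header token before the first
#' whitespace; the sequence is uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A [mito_reference()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("FASTA file contains no sequence records: ", path)
  }
  if (length(seqs) > 1L) {
    extra <- sub("\\s.*$", "", names(seqs)[-1L])
    stop(
      "multiple contigs in FASTA (single-contig tool); extra contig(s): ",
      paste(extra, collapse = ", ")
    )
  }
  nm <- sub("\\s.*$", "", names(seqs)[1L])
  mito_reference(nm, as.character(seqs[[1L]]))
}

#' Write a reference to FASTA
#'
#' @param reference A [mito_reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reference, path) {
  stopifnot(inherits(reference, "mito_reference"))
  x <- Biostrings::DNAStringSet(reference$sequence)
  names(x) <- reference$name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
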