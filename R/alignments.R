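## Aligned reads are carried as a plain data.frame with columns
##   qname, flag, rname, pos, mapq, cigar, seq, qual
## (qual is the raw Phred+33 string). Attributes on the frame:
##   "contigs"   - contig names declared in the header plus those seen
##   "malformed" - reads dropped for violating len(seq) == CIGAR query span
## SAM text is the interchange format; BAM is read through Rsamtools when
## the file extension is .bam.

FLAG_UNMAPPED <- 0x4L
FLAG_REVERSE <- 0x10L
FLAG_SECONDARY <- 0x100L
FLAG_DUPLICATE <- 0x400L
FLAG_SUPPLEMENTARY <- 0x800L

empty_reads <- function() {
  data.frame(
    qname = character(0), flag = integer(0), rname = character(0),
    pos = integer(0), mapq = integer(0), cigar = character(0),
    seq = character(0), qual = character(0), stringsAsFactors = FALSE
  )
}

#' Query-consuming length of CIGAR strings
#'
#' Sums the lengths of M/I/S/=/X operations; this must equal the read
#' sequence length for a well-formed record.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of query lengths (NA for `*`).
#' @keywords internal
cigar_query_length <- function(cigar) {
  out <- rep(NA_integer_, length(cigar))
  simple <- grepl("^[0-9]+M$", cigar)
  out[simple] <- as.integer(sub("M$", "", cigar[simple]))
  rest <- which(!simple & cigar != "*")
  if (length(rest)) {
    out[rest] <- vapply(cigar[rest], function(cg) {
      ops <- cigar_ops(cg)
      sum(ops$len[ops$op %in% c("M", "I", "S", "=", "X")])
    }, integer(1), USE.NAMES = FALSE)
  }
  out
}

## Split one CIGAR string into op lengths and op codes.
cigar_ops <- function(cigar) {
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  list(len = len, op = op)
}

#' Read aligned reads from SAM or BAM
#'
#' Unmapped, secondary, supplementary and (by default) duplicate-flagged
#' reads are skipped, as are records whose sequence length disagrees with
#' the CIGAR query span; the latter are counted in the `"malformed"`
#' attribute so QC can surface them. The `"contigs"` attribute collects the
#' contig names declared in the header together with those observed on
#' retained reads.
#'
#' @param path Path to a SAM text file (or BAM, requires Rsamtools).
#' @param region Optional contig name; only reads mapped to it are returned.
#' @param keep_duplicates Keep duplicate-flagged reads (default `FALSE`).
#' @return A data.frame of reads (see file header) with attributes
#'   `contigs` and `malformed`.
#' @export
read_alignments <- function(path, region = NULL, keep_duplicates = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    reads <- read_bam_records(path)
    header_contigs <- attr(reads, "contigs")
  } else {
    lines <- readLines(path)
    header <- lines[startsWith(lines, "@")]
    body <- lines[!startsWith(lines, "@") & nzchar(lines)]
    sq <- header[startsWith(header, "@SQ")]
    header_contigs <- sub("^SN:", "", unlist(regmatches(sq, gregexpr("SN:[^\t]+", sq))))
    header_contigs <- sub("^SN:", "", header_contigs)
    if (length(body) == 0L) {
      reads <- empty_reads()
    } else {
      fields <- strsplit(body, "\t", fixed = TRUE)
      nf <- lengths(fields)
      fields <- fields[nf >= 11L]
      get <- function(i) vapply(fields, `[[`, character(1), i)
      reads <- data.frame(
        qname = get(1), flag = as.integer(get(2)), rname = get(3),
        pos = as.integer(get(4)), mapq = as.integer(get(5)), cigar = get(6),
        seq = get(10), qual = get(11), stringsAsFactors = FALSE
      )
    }
  }

  drop_flags <- FLAG_UNMAPPED + FLAG_SECONDARY + FLAG_SUPPLEMENTARY
  keep <- bitwAnd(reads$flag, drop_flags) == 0L & reads$rname != "*" & reads$pos >= 1L
  if (!keep_duplicates) {
    keep <- keep & bitwAnd(reads$flag, FLAG_DUPLICATE) == 0L
  }
  reads <- reads[keep, , drop = FALSE]

  qlen <- cigar_query_length(reads$cigar)
  ok <- !is.na(qlen) & qlen == nchar(reads$seq) & nchar(reads$seq) == nchar(reads$qual)
  malformed <- sum(!ok)
  reads <- reads[ok, , drop = FALSE]

  contigs <- union(header_contigs, unique(reads$rname))
  if (!is.null(region)) {
    reads <- reads[reads$rname == region, , drop = FALSE]
  }
  rownames(reads) <- NULL
  attr(reads, "contigs") <- contigs
  attr(reads, "malformed") <- malformed
  reads
}

read_bam_records <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("reading BAM requires the Rsamtools package; convert to SAM text instead")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual")
  )
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  reads <- data.frame(
    qname = b$qname, flag = as.integer(b$flag),
    rname = as.character(b$rname), pos = as.integer(b$pos),
    mapq = as.integer(b$mapq), cigar = b$cigar,
    seq = as.character(b$seq), qual = as.character(b$qual),
    stringsAsFactors = FALSE
  )
  reads$rname[is.na(reads$rname)] <- "*"
  reads$pos[is.na(reads$pos)] <- 0L
  reads$cigar[is.na(reads$cigar)] <- "*"
  hdr <- Rsamtools::scanBamHeader(path)[[1]]$targets
  attr(reads, "contigs") <- names(hdr)
  reads
}

#' Write reads to SAM text
#'
#' Emits a minimal valid SAM with `@HD` and `@SQ` header lines for the
#' given reference.
#'
#' @param reads Read data.frame as produced by [read_alignments()] or
#'   [simulate_reads()].
#' @param reference A [mito_reference()] used for the `@SQ` line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, reference, path) {
  stopifnot(inherits(reference, "mito_reference"))
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", reference$name, reference$length)
  )
  if (nrow(reads)) {
    body <- paste(
      reads$qname, reads$flag, reads$rname, reads$pos, reads$mapq,
      reads$cigar, "*", 0L, 0L, reads$seq, reads$qual,
      sep = "\t"
    )
  } else {
    body <- character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

## Phred+33 helpers shared by the simulator and the pileup engine.
qual_string_to_phred <- function(qual) {
  utf8ToInt(qual) - 33L
}

phred_to_qual_string <- function(q) {
  intToUtf8(q + 33L)
}
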