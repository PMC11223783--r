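## Minimal VCF 4.2 reader/writer for the biallelic-call schema this toolkit
## uses. Records travel as a data.frame with columns
##   chrom, pos, id, ref, alt, qual, filter, info, gt, dp, af
## where `alt` may hold a comma-separated list before multiallelic
## splitting. INFO keys MEAN_BQ and SRC and FORMAT keys GT/DP/AF are parsed
## into their own columns; anything else stays verbatim in `info`.

VCF_FILTERS <- c(
  PASS = "All filters passed",
  low_vaf_for_coverage = "Alt read count below the minimal trusted count for the site's coverage and base quality",
  strand_bias = "Alt allele support heavily skewed to one strand"
)

VCF_INFO_KEYS <- c(
  MEAN_BQ = "Mean Phred base quality of alt-supporting observations",
  SRC = "Source caller"
)

empty_vcf_records <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), id = character(0),
    ref = character(0), alt = character(0), qual = numeric(0),
    filter = character(0), info = character(0), gt = character(0),
    dp = integer(0), af = numeric(0), stringsAsFactors = FALSE
  )
}

vcf_header_lines <- function(reference, sample = "SAMPLE") {
  c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", reference$name, reference$length),
    sprintf("##FILTER=<ID=%s,Description=\"%s\">",
            names(VCF_FILTERS)[-1L], VCF_FILTERS[-1L]),
    sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
            names(VCF_INFO_KEYS), c("Float", "String"), VCF_INFO_KEYS),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample), collapse = "\t")
  )
}

#' Write VCF 4.2
#'
#' Records must be position-sorted and may only use FILTER/INFO keys
#' declared in the header (`PASS`, `low_vaf_for_coverage`, `strand_bias`;
#' `MEAN_BQ`, `SRC`). AF is written to 4 decimal places.
#'
#' @param records VCF record data.frame (see file header); an empty frame
#'   yields a header-only valid VCF.
#' @param reference A [mito_reference()] declared in the `##contig` line.
#' @param path Output path.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, reference, path, sample = "SAMPLE") {
  stopifnot(inherits(reference, "mito_reference"))
  lines <- vcf_header_lines(reference, sample)
  if (nrow(records)) {
    if (is.unsorted(records$pos)) {
      stop("VCF records must be sorted by position")
    }
    filt_keys <- unique(unlist(strsplit(records$filter, ";", fixed = TRUE)))
    bad <- setdiff(filt_keys, c(names(VCF_FILTERS), "."))
    if (length(bad)) stop("undeclared FILTER key(s): ", paste(bad, collapse = ", "))
    info_keys <- unlist(regmatches(records$info, gregexpr("(^|;)[A-Za-z_]+", records$info)))
    info_keys <- setdiff(unique(sub("^;", "", info_keys)), "")
    bad <- setdiff(info_keys, c(names(VCF_INFO_KEYS), "."))
    if (length(bad)) stop("undeclared INFO key(s): ", paste(bad, collapse = ", "))
    af <- ifelse(is.na(records$af), ".", sprintf("%.4f", records$af))
    dp <- ifelse(is.na(records$dp), ".", as.character(records$dp))
    gt <- ifelse(is.na(records$gt) | records$gt == "", ".", records$gt)
    body <- paste(
      records$chrom, records$pos,
      ifelse(is.na(records$id) | records$id == "", ".", records$id),
      records$ref, records$alt,
      ifelse(is.na(records$qual), ".", format(records$qual, trim = TRUE)),
      ifelse(is.na(records$filter) | records$filter == "", ".", records$filter),
      ifelse(is.na(records$info) | records$info == "", ".", records$info),
      "GT:DP:AF", paste(gt, dp, af, sep = ":"),
      sep = "\t"
    )
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF produced by this toolkit (or any simple single-sample VCF)
#'
#' @param path Path to a VCF text file.
#' @return VCF record data.frame; `alt` keeps multiallelic records as a
#'   comma-separated string.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(body)) {
    return(empty_vcf_records())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[[i]] else ".", character(1))
  fmt <- get(9)
  smp <- get(10)
  parse_fmt <- function(key) {
    mapply(function(f, s) {
      ks <- strsplit(f, ":", fixed = TRUE)[[1]]
      vs <- strsplit(s, ":", fixed = TRUE)[[1]]
      i <- match(key, ks)
      if (is.na(i) || i > length(vs)) NA_character_ else vs[[i]]
    }, fmt, smp, USE.NAMES = FALSE)
  }
  qual <- suppressWarnings(as.numeric(get(6)))
  data.frame(
    chrom = get(1), pos = as.integer(get(2)), id = get(3),
    ref = get(4), alt = get(5), qual = qual,
    filter = get(7), info = get(8),
    gt = parse_fmt("GT"),
    dp = suppressWarnings(as.integer(parse_fmt("DP"))),
    af = suppressWarnings(as.numeric(parse_fmt("AF"))),
    stringsAsFactors = FALSE
  )
}

## Pull one key out of an INFO string; NA when absent.
info_field <- function(info, key) {
  vapply(info, function(x) {
    m <- regmatches(x, regexpr(paste0("(^|;)", key, "=[^;]*"), x))
    if (!length(m)) NA_character_ else sub(paste0("^.*", key, "="), "", m)
  }, character(1), USE.NAMES = FALSE)
}
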