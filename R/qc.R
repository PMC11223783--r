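#' Default set of accepted mitochondrial contig names
#' @export
MITO_CONTIGS <- c("chrM", "MT", "chrMT", "NC_012920.1", "rCRS")

#' Per-position depth and mean coverage
#'
#' Depth counts reference-aligned bases (CIGAR M/=/X) passing the base- and
#' mapping-quality floors; deletions and clips add nothing. Mean coverage
#' is total passing bases over the reference length.
#'
#' @param reads Read data.frame.
#' @param reference A [mito_reference()].
#' @param min_baseq,min_mapq Quality floors (defaults 0: raw coverage).
#' @return List with `depth` (integer vector over positions) and `mean`.
#' @export
mean_coverage <- function(reads, reference, min_baseq = 0L, min_mapq = 0L) {
  pl <- build_pileup(reads, reference, min_baseq = min_baseq, min_mapq = min_mapq)
  list(depth = pl$depth, mean = sum(pl$depth) / reference$length)
}

#' Validate one sample before variant calling
#'
#' All checks always run and every violated requirement is reported, so a
#' failing sample comes back with the complete list of reasons. Statistics
#' are filled in regardless of pass/fail.
#'
#' @param reads Read data.frame (or a path readable by
#'   [read_alignments()]).
#' @param reference A [mito_reference()].
#' @param sample_id Identifier used in reports.
#' @param expected_contigs Accepted contig names (default [MITO_CONTIGS]).
#' @param min_mean_coverage Minimum mean coverage (default 50).
#' @param min_mean_baseq,min_mean_mapq Minimum mean base/mapping quality
#'   (defaults 10).
#' @return A `mito_qc` list: sample_id, passed, exclusion_reasons,
#'   contig_seen, mean/median coverage, mean mapq/baseq, pct_bases_ge_q20,
#'   read_count, malformed_reads, mean_detectable_vaf (NA until filled by
#'   the coverage model).
#' @export
validate_sample <- function(reads, reference, sample_id = "sample",
                            expected_contigs = MITO_CONTIGS,
                            min_mean_coverage = 50,
                            min_mean_baseq = 10,
                            min_mean_mapq = 10) {
  if (is.character(reads)) {
    reads <- tryCatch(read_alignments(reads), error = function(e) e)
    if (inherits(reads, "error")) {
      return(structure(list(
        sample_id = sample_id, passed = FALSE,
        exclusion_reasons = "unreadable", contig_seen = NA_character_,
        mean_coverage = NA_real_, median_coverage = NA_real_,
        mean_mapq = NA_real_, mean_baseq = NA_real_,
        pct_bases_ge_q20 = NA_real_, read_count = 0L,
        malformed_reads = 0L, mean_detectable_vaf = NA_real_
      ), class = "mito_qc"))
    }
  }
  reasons <- character(0)
  contig <- if (nrow(reads)) names(sort(table(reads$rname), decreasing = TRUE))[1] else NA_character_
  if (is.na(contig) || !(contig %in% expected_contigs)) {
    reasons <- c(reasons, "wrong_contig")
  }
  cov <- mean_coverage(reads, reference)
  if (cov$mean < min_mean_coverage) reasons <- c(reasons, "low_coverage")

  if (nrow(reads)) {
    quals <- utf8ToInt(paste(reads$qual, collapse = "")) - 33L
    mean_bq <- mean(quals)
    pct_q20 <- 100 * mean(quals >= 20L)
    mean_mq <- mean(reads$mapq)
  } else {
    mean_bq <- NA_real_; pct_q20 <- NA_real_; mean_mq <- NA_real_
  }
  if (!is.na(mean_bq) && mean_bq < min_mean_baseq) reasons <- c(reasons, "low_baseq")
  if (!is.na(mean_mq) && mean_mq < min_mean_mapq) reasons <- c(reasons, "low_mapq")

  structure(list(
    sample_id = sample_id,
    passed = length(reasons) == 0L,
    exclusion_reasons = reasons,
    contig_seen = contig,
    mean_coverage = cov$mean,
    median_coverage = stats::median(cov$depth),
    mean_mapq = mean_mq,
    mean_baseq = mean_bq,
    pct_bases_ge_q20 = pct_q20,
    read_count = nrow(reads),
    malformed_reads = attr(reads, "malformed") %||% 0L,
    mean_detectable_vaf = NA_real_
  ), class = "mito_qc")
}

#' @export
print.mito_qc <- function(x, ...) {
  status <- if (x$passed) "PASSED" else
    paste0("EXCLUDED (", paste(x$exclusion_reasons, collapse = ", "), ")")
  cat(sprintf("<mito_qc> %s: %s\n", x$sample_id, status))
  cat(sprintf("  contig %s; %d reads (%d malformed); mean coverage %.1fx (median %.0fx)\n",
              x$contig_seen, x$read_count, x$malformed_reads,
              x$mean_coverage, x$median_coverage))
  cat(sprintf("  mean mapq %.1f; mean baseq %.1f; %.1f%% bases >= Q20",
              x$mean_mapq, x$mean_baseq, x$pct_bases_ge_q20))
  if (!is.na(x$mean_detectable_vaf)) {
    cat(sprintf("; mean detectable VAF %.4f", x$mean_detectable_vaf))
  }
  cat("\n")
  invisible(x)
}

#' Write QC reports as per-sample JSON and a combined TSV
#'
#' @param qc_list List of `mito_qc` objects.
#' @param dir Output directory (created if needed).
#' @return Path of the combined TSV, invisibly.
#' @export
write_qc_reports <- function(qc_list, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(qc_list, function(q) {
    jsonlite::write_json(
      q[names(q)], file.path(dir, paste0(q$sample_id, ".qc.json")),
      auto_unbox = TRUE, digits = NA, null = "null", na = "null"
    )
    data.frame(
      sample_id = q$sample_id, passed = q$passed,
      reasons = paste(q$exclusion_reasons, collapse = ";"),
      contig = q$contig_seen, mean_coverage = q$mean_coverage,
      median_coverage = q$median_coverage, mean_mapq = q$mean_mapq,
      mean_baseq = q$mean_baseq, pct_bases_ge_q20 = q$pct_bases_ge_q20,
      read_count = q$read_count, malformed_reads = q$malformed_reads,
      mean_detectable_vaf = q$mean_detectable_vaf,
      stringsAsFactors = FALSE
    )
  })
  tsv <- file.path(dir, "qc_summary.tsv")
  utils::write.table(do.call(rbind, rows), tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(tsv)
}
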