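## Per-sample workflow: validate -> (optional subsample) -> pileup ->
## call (snv | indel | fusion) -> (optional min-VAF flagging) -> report.
## Samples are independent, so any concurrent batch execution must give
## output identical to sequential execution; everything here is pure given
## (inputs, parameters, seed).

#' Convert a call set to VCF records
#'
#' @param calls A `mito_calls` data.frame.
#' @param reference A [mito_reference()].
#' @return VCF record data.frame for [write_vcf()].
#' @export
calls_to_vcf_records <- function(calls, reference) {
  if (!nrow(calls)) return(empty_vcf_records())
  data.frame(
    chrom = reference$name,
    pos = calls$pos,
    id = ".",
    ref = calls$ref,
    alt = calls$alt,
    qual = NA_real_,
    filter = ifelse(calls$filter == "" | is.na(calls$filter), "PASS", calls$filter),
    info = sprintf("MEAN_BQ=%.2f;SRC=%s", calls$mean_baseq, calls$src),
    gt = calls$gt,
    dp = calls$depth,
    af = calls$vaf,
    stringsAsFactors = FALSE
  )
}

#' Convert VCF records (e.g. an external indel VCF) to a call set
#'
#' Multiallelic records are split first; variant types are assigned by
#' allele length.
#'
#' @param records VCF record data.frame from [read_vcf()].
#' @param src Source tag stored on the calls.
#' @return A `mito_calls` data.frame.
#' @export
vcf_records_to_calls <- function(records, src = "external") {
  if (!nrow(records)) {
    out <- empty_calls()
    class(out) <- c("mito_calls", "data.frame")
    return(out)
  }
  split_rows <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    split_multiallelic(records[i, , drop = FALSE])
  }))
  info_src <- info_field(split_rows$info, "SRC")
  info_bq <- suppressWarnings(as.numeric(info_field(split_rows$info, "MEAN_BQ")))
  out <- data.frame(
    pos = split_rows$pos,
    ref = split_rows$ref,
    alt = split_rows$alt,
    type = allele_type(split_rows$ref, split_rows$alt),
    vaf = ifelse(is.na(split_rows$af), 1, split_rows$af),
    depth = ifelse(is.na(split_rows$dp), NA_integer_, split_rows$dp),
    n_alt = NA_integer_, alt_fwd = NA_integer_, alt_rev = NA_integer_,
    mean_baseq = info_bq,
    gt = ifelse(is.na(split_rows$gt), "0/1", split_rows$gt),
    filter = ifelse(split_rows$filter %in% c(".", ""), "PASS", split_rows$filter),
    src = ifelse(is.na(info_src), src, info_src),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mito_calls", "data.frame")
  out
}

#' Run the full per-sample workflow
#'
#' @param reads Read data.frame or a SAM/BAM path.
#' @param reference A [mito_reference()].
#' @param mode One of "snv" (Bayesian caller only), "indel" (pileup indel
#'   caller only), "fusion" (both, merged with indels winning positional
#'   conflicts).
#' @param sample_id Identifier used in reports.
#' @param priors A [mito_priors()].
#' @param min_vaf Heteroplasmy detection floor (default 0.02).
#' @param min_depth Minimum depth to call (default 10).
#' @param min_baseq,min_mapq Pileup quality floors (defaults 20).
#' @param subsample If TRUE, subsample to `target_cov` before calling.
#' @param target_cov Subsampling target coverage (default 2000).
#' @param subsample_seed Seed for the subsampling hash.
#' @param min_vaf_check If TRUE, flag calls with the binomial coverage
#'   model and fill `mean_detectable_vaf` in QC.
#' @param alpha Significance level for the coverage model (default 0.05).
#' @param qc_thresholds Named list overriding [validate_sample()] defaults
#'   (expected_contigs, min_mean_coverage, min_mean_baseq, min_mean_mapq).
#' @return A `mito_result` list: `sample_id`, `status` ("called" or
#'   "excluded"), `qc` (`mito_qc`), `calls` (`mito_calls` or NULL),
#'   `summary` (named list for the batch report).
#' @export
run_sample <- function(reads, reference, mode = c("fusion", "snv", "indel"),
                       sample_id = "sample", priors = mito_priors(),
                       min_vaf = 0.02, min_depth = 10L,
                       min_baseq = 20L, min_mapq = 20L,
                       subsample = FALSE, target_cov = 2000,
                       subsample_seed = MITOVAR_SUBSAMPLE_SEED,
                       min_vaf_check = FALSE, alpha = 0.05,
                       qc_thresholds = list()) {
  mode <- match.arg(mode)
  if (is.character(reads)) {
    reads_or_err <- tryCatch(read_alignments(reads), error = function(e) e)
    if (inherits(reads_or_err, "error")) {
      qc <- validate_sample(reads, reference, sample_id)
      return(mito_result(sample_id, "excluded", qc, NULL, mode,
                         params = list()))
    }
    reads <- reads_or_err
  }
  qc_args <- c(list(reads = reads, reference = reference, sample_id = sample_id),
               qc_thresholds)
  qc <- do.call(validate_sample, qc_args)
  params <- list(
    mode = mode, min_vaf = min_vaf, min_depth = min_depth,
    min_baseq = min_baseq, min_mapq = min_mapq,
    subsample = subsample, target_cov = target_cov,
    subsample_seed = subsample_seed,
    min_vaf_check = min_vaf_check, alpha = alpha
  )
  if (!qc$passed) {
    return(mito_result(sample_id, "excluded", qc, NULL, mode, params))
  }
  if (subsample) {
    reads <- subsample_to_coverage(reads, reference, target_cov, subsample_seed)
  }
  pileup <- build_pileup(reads, reference, min_baseq = min_baseq, min_mapq = min_mapq)
  snv <- if (mode %in% c("snv", "fusion")) {
    normalize_calls(call_snvs(pileup, priors, min_vaf = min_vaf,
                              min_depth = min_depth), reference)
  } else NULL
  ind <- if (mode %in% c("indel", "fusion")) {
    normalize_calls(call_indels(pileup, min_vaf = min_vaf,
                                min_depth = min_depth), reference)
  } else NULL
  calls <- switch(mode,
    snv = snv,
    indel = ind,
    fusion = merge_fusion(snv, ind, reference)
  )
  class(calls) <- c("mito_calls", "data.frame")
  if (min_vaf_check) {
    calls <- flag_calls(calls, alpha = alpha)
    qc$mean_detectable_vaf <- sample_mean_detectable_vaf(pileup, alpha = alpha)
  }
  mito_result(sample_id, "called", qc, calls, mode, params)
}

mito_result <- function(sample_id, status, qc, calls, mode, params) {
  summary <- list(
    sample = sample_id, mode = mode, status = status,
    passed = isTRUE(qc$passed),
    reasons = paste(qc$exclusion_reasons, collapse = ";"),
    n_snv = if (is.null(calls)) 0L else sum(calls$type == "SNV"),
    n_indel = if (is.null(calls)) 0L else sum(calls$type %in% c("INS", "DEL")),
    n_flagged = if (is.null(calls)) 0L else sum(calls$filter != "PASS"),
    mean_coverage = qc$mean_coverage,
    mean_detectable_vaf = qc$mean_detectable_vaf,
    params = params
  )
  structure(list(sample_id = sample_id, status = status, qc = qc,
                 calls = calls, summary = summary),
            class = "mito_result")
}

#' @export
print.mito_result <- function(x, ...) {
  cat(sprintf("<mito_result> %s [%s]\n", x$sample_id, x$status))
  print(x$qc)
  if (!is.null(x$calls)) print(x$calls)
  invisible(x)
}

#' Summarize a batch of per-sample results
#'
#' One row per sample (passed/excluded, reasons, coverage, call counts);
#' the parameter set used is serialized into the JSON so a run can be
#' reproduced from its report.
#'
#' @param results List of `mito_result` objects.
#' @param dir Optional output directory; when given, writes
#'   `batch_summary.tsv` and `batch_summary.json`.
#' @return The batch data.frame, invisibly when writing.
#' @export
summarize_batch <- function(results, dir = NULL) {
  stopifnot(length(results) >= 1L)
  rows <- do.call(rbind, lapply(results, function(r) {
    s <- r$summary
    data.frame(
      sample = s$sample, mode = s$mode, status = s$status,
      passed = s$passed, reasons = s$reasons,
      n_snv = s$n_snv, n_indel = s$n_indel, n_flagged = s$n_flagged,
      mean_coverage = s$mean_coverage,
      mean_detectable_vaf = s$mean_detectable_vaf,
      stringsAsFactors = FALSE
    )
  }))
  rownames(rows) <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(rows, file.path(dir, "batch_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(samples = rows, params = results[[1]]$summary$params),
      file.path(dir, "batch_summary.json"),
      auto_unbox = TRUE, digits = NA, na = "null", dataframe = "rows"
    )
    return(invisible(rows))
  }
  rows
}
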