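#' Regenerate the gold-standard benchmark and score each calling mode
#'
#' Simulates `n_samples` samples on a seeded reference, each carrying
#' `n_snv` heteroplasmic SNVs and `n_indel` heteroplasmic indels at target
#' VAFs drawn uniformly from `[vaf_min, vaf_max]`, sequences them at
#' `coverage` with a constant-quality Phred error model, runs the requested
#' calling modes on each sample and scores calls against the truth set.
#' All per-sample seeds derive from `seed`, so one integer reproduces the
#' entire experiment.
#'
#' @param n_samples Number of samples (default 30).
#' @param coverage Mean coverage per sample (default 2000).
#' @param n_snv,n_indel Spiked variant counts per sample (defaults 35, 8).
#' @param ref_length Reference length in bp (default 16569).
#' @param vaf_min,vaf_max Target VAF range (defaults 0.02, 0.5).
#' @param read_len,base_qual Read length and Phred quality (150, 30).
#' @param modes Calling modes to score (default snv, indel and fusion).
#' @param min_vaf Detection floor passed to the callers (default 0.02).
#' @param seed Master seed.
#' @return A `mito_benchmark`: list with `results` (long data.frame:
#'   sample, mode, class, all_sites, tp, fp, fn), `truth_sizes` (per-sample
#'   truth composition) and the generating parameters.
#' @export
run_benchmark <- function(n_samples = 30L, coverage = 2000,
                          n_snv = 35L, n_indel = 8L, ref_length = 16569L,
                          vaf_min = 0.02, vaf_max = 0.5,
                          read_len = 150L, base_qual = 30L,
                          modes = c("snv", "indel", "fusion"),
                          min_vaf = 0.02, seed = 1L) {
  modes <- match.arg(modes, several.ok = TRUE)
  reference <- simulate_reference(ref_length, seed = seed)
  rows <- list()
  truth_sizes <- list()
  for (i in seq_len(n_samples)) {
    sid <- sprintf("sample%03d", i)
    truth <- spike_variants(reference, n_snv = n_snv, n_indel = n_indel,
                            vaf_min = vaf_min, vaf_max = vaf_max,
                            seed = seed + i)
    reads <- simulate_reads(reference, truth, coverage = coverage,
                            read_len = read_len, base_qual = base_qual,
                            seed = seed + 100000L + i)
    pileup <- build_pileup(reads, reference)
    snv <- normalize_calls(call_snvs(pileup, min_vaf = min_vaf), reference)
    ind <- normalize_calls(call_indels(pileup, min_vaf = min_vaf), reference)
    calls_by_mode <- list(
      snv = snv, indel = ind,
      fusion = merge_fusion(snv, ind, reference)
    )
    truth_sizes[[i]] <- data.frame(
      sample = sid, n_truth = nrow(truth),
      n_truth_snv = sum(truth$type == "SNV"),
      n_truth_indel = sum(truth$type %in% c("INS", "DEL")),
      stringsAsFactors = FALSE
    )
    for (mode in modes) {
      ev <- evaluate_calls(calls_by_mode[[mode]], truth)
      for (cls in c("all", "snv", "indel")) {
        s <- ev[[cls]]
        rows[[length(rows) + 1L]] <- data.frame(
          sample = sid, mode = mode, class = cls,
          all_sites = s$all_sites, tp = s$tp, fp = s$fp, fn = s$fn,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  structure(list(
    results = do.call(rbind, rows),
    truth_sizes = do.call(rbind, truth_sizes),
    params = list(n_samples = n_samples, coverage = coverage, n_snv = n_snv,
                  n_indel = n_indel, ref_length = ref_length,
                  vaf_min = vaf_min, vaf_max = vaf_max, read_len = read_len,
                  base_qual = base_qual, min_vaf = min_vaf, seed = seed)
  ), class = "mito_benchmark")
}

#' Benchmark means in the layout of a mode-by-class results table
#'
#' @param x A `mito_benchmark`.
#' @return data.frame with mode, class and per-sample means of all_sites,
#'   tp, fp, fn.
#' @export
benchmark_table <- function(x) {
  stopifnot(inherits(x, "mito_benchmark"))
  r <- x$results
  out <- aggregate(r[, c("all_sites", "tp", "fp", "fn")],
                   by = list(mode = r$mode, class = r$class), FUN = mean)
  out[order(out$mode, out$class), ]
}

#' @export
print.mito_benchmark <- function(x, ...) {
  cat(sprintf(
    "<mito_benchmark> %d sample(s) at %gx, %d SNV + %d indel spikes each\n",
    x$params$n_samples, x$params$coverage, x$params$n_snv, x$params$n_indel
  ))
  print(benchmark_table(x), row.names = FALSE)
  invisible(x)
}
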