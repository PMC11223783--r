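## Binomial minimal-trusted-VAF model. At a site with depth N and
## per-base error probability p (from the mean base quality), the number of
## alt-looking reads produced by sequencing error alone is X ~ Binomial(N, p).
## The minimal trusted alt-read count k* is the smallest k whose upper tail
## P(X >= k) drops below the significance level alpha; the minimal trusted
## VAF is k*/N. Observed variants with fewer than k* alt reads are flagged
## (not removed).

#' Minimal significant alt-read count under a binomial error model
#'
#' Smallest integer k with P(X >= k) < alpha for X ~ Binomial(N, p),
#' computed with the stable upper-tail `pbinom(..., lower.tail = FALSE)`.
#' When even k = N does not reach significance, N + 1 is returned and the
#' result is unachievable at this depth.
#'
#' @param N Depth (>= 1).
#' @param p Per-base error probability in [0, 1).
#' @param alpha Significance level in (0, 1).
#' @return Integer k* in 1..N+1.
#' @export
min_alt_reads <- function(N, p, alpha = 0.05) {
  stopifnot(N >= 1, p >= 0, p < 1, alpha > 0, alpha < 1)
  if (p == 0) return(1L)           # any alt read is significant
  tail_ge <- function(k) stats::pbinom(k - 1, N, p, lower.tail = FALSE)
  ## bracket with the quantile function, then settle by scanning
  k <- stats::qbinom(1 - alpha, N, p) + 1L
  while (k > 1L && tail_ge(k - 1L) < alpha) k <- k - 1L
  while (k <= N && tail_ge(k) >= alpha) k <- k + 1L
  if (k > N && tail_ge(N) >= alpha) return(N + 1L)
  as.integer(k)
}

#' Minimal trusted VAF for a site
#'
#' Composition of [phred_to_error()] and [min_alt_reads()]:
#' `min_vaf = k*/N` for error probability `p = phred_to_error(mean_baseq)`.
#'
#' @param N Depth.
#' @param mean_baseq Mean Phred base quality at the site.
#' @param alpha Significance level.
#' @return List with `N`, `mean_baseq`, `error_p`, `alpha`, `k_star`,
#'   `min_vaf` (NA with `achievable = FALSE` when k* = N + 1 or N = 0).
#' @export
min_trusted_vaf <- function(N, mean_baseq, alpha = 0.05) {
  if (is.na(N) || N < 1) {
    return(list(N = N, mean_baseq = mean_baseq, error_p = NA_real_,
                alpha = alpha, k_star = NA_integer_, min_vaf = NA_real_,
                achievable = FALSE))
  }
  p <- phred_to_error(mean_baseq)
  k <- min_alt_reads(N, p, alpha)
  achievable <- k <= N
  list(
    N = as.integer(N), mean_baseq = mean_baseq, error_p = p, alpha = alpha,
    k_star = k, min_vaf = if (achievable) k / N else NA_real_,
    achievable = achievable
  )
}

#' Flag calls whose alt support is below the minimal trusted count
#'
#' Each call whose alt read count is below k*(depth, error p, alpha) gains
#' the FILTER value `low_vaf_for_coverage`; no call is removed. The error
#' probability uses the mean base quality of the alt-supporting
#' observations carried on the call (falling back to the column mean when
#' absent).
#'
#' @param calls A `mito_calls` data.frame.
#' @param alpha Significance level (default 0.05).
#' @return The call set with updated `filter` plus columns `k_star` and
#'   `min_vaf`.
#' @export
flag_calls <- function(calls, alpha = 0.05) {
  if (!nrow(calls)) {
    calls$k_star <- integer(0)
    calls$min_vaf <- numeric(0)
    return(calls)
  }
  ks <- integer(nrow(calls))
  mv <- numeric(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    r <- min_trusted_vaf(calls$depth[i], calls$mean_baseq[i], alpha)
    ks[i] <- r$k_star
    mv[i] <- if (r$achievable) r$min_vaf else NA_real_
  }
  low <- calls$n_alt < ks
  calls$filter <- ifelse(
    low,
    ifelse(calls$filter == "PASS" | calls$filter == "",
           "low_vaf_for_coverage",
           paste(calls$filter, "low_vaf_for_coverage", sep = ";")),
    calls$filter
  )
  calls$k_star <- ks
  calls$min_vaf <- mv
  calls
}

#' Mean detectable VAF of a sample
#'
#' Mean over covered positions (depth > 0) of the per-position minimal
#' trusted VAF; reported in the QC output as the sample's detection floor.
#'
#' @param pileup A `mito_pileup`.
#' @param alpha Significance level (default 0.05).
#' @return Fraction in (0, 1], or NA when no position is covered.
#' @export
sample_mean_detectable_vaf <- function(pileup, alpha = 0.05) {
  stopifnot(inherits(pileup, "mito_pileup"))
  cov <- which(pileup$depth > 0L)
  if (!length(cov)) return(NA_real_)
  N <- pileup$depth[cov]
  ## positions share few unique (depth, mean quality) pairs; solve each once
  q <- round(pileup$mean_baseq[cov], 2)
  key <- paste(N, q)
  uk <- !duplicated(key)
  vals <- mapply(function(n, qq) {
    r <- min_trusted_vaf(n, qq, alpha)
    if (r$achievable) r$min_vaf else 1
  }, N[uk], q[uk])
  mean(vals[match(key, key[uk])])
}
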