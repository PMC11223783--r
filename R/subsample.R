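## Deterministic read subsampling. The keep decision for a read is a pure
## function of (seed, read name): a 32-bit FNV-1a hash of the name, mixed
## with the seed and mapped to [0, 1). Consequences: re-runs with the same
## seed keep byte-identical read sets, the kept set is invariant under
## input reordering, and paired reads sharing a name travel together.

#' Default static subsampling seed
#' @export
MITOVAR_SUBSAMPLE_SEED <- 20231123L

#' Fraction of reads required to hit a target mean coverage
#'
#' @param mean_cov Observed mean coverage (x).
#' @param target_cov Target mean coverage (x), default 2000.
#' @return `min(1, target_cov / mean_cov)`; 1 when `mean_cov` is 0.
#' @export
subsample_fraction <- function(mean_cov, target_cov = 2000) {
  stopifnot(mean_cov >= 0, target_cov > 0)
  if (mean_cov == 0) return(1)
  min(1, target_cov / mean_cov)
}

## Vectorized FNV-1a over read names (32-bit arithmetic carried in doubles,
## reduced mod 2^32 each step so results are exact), then a final
## seed-dependent scramble. Returns values in [0, 1).
name_hash_unit <- function(names, seed) {
  two32 <- 4294967296
  n <- length(names)
  h <- rep(2166136261, n)
  lens <- nchar(names)
  starts <- cumsum(c(0L, lens[-n])) + 1L
  all_codes <- utf8ToInt(paste(names, collapse = ""))
  for (j in seq_len(max(c(0L, lens)))) {
    active <- which(lens >= j)
    cj <- all_codes[starts[active] + j - 1L]
    ## xor on the low 8 bits, exact in doubles
    low <- h[active] %% 256
    h[active] <- fnv_mul(h[active] - low + bitwXor(as.integer(low), cj))
  }
  ## seed mix: two more multiply rounds
  s <- as.double(seed %% two32)
  h <- fnv_mul((h + s) %% two32)
  h <- fnv_mul((h + floor(s / 65536) + 1) %% two32)
  h / two32
}

## (h * 16777619) mod 2^32 without losing precision: split h into 16-bit
## halves so every product stays below 2^53.
fnv_mul <- function(h) {
  two32 <- 4294967296
  hi <- floor(h / 65536)
  lo <- h %% 65536
  (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% two32
}

#' Deterministically subsample reads by name hash
#'
#' @param reads Read data.frame.
#' @param fraction Keep probability in (0, 1]; 1 returns the input as-is.
#' @param seed Integer seed (default [MITOVAR_SUBSAMPLE_SEED]).
#' @return The kept subset of `reads` in input order, attributes preserved.
#' @export
subsample_reads <- function(reads, fraction, seed = MITOVAR_SUBSAMPLE_SEED) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1 || !nrow(reads)) return(reads)
  u <- name_hash_unit(reads$qname, seed)
  out <- reads[u < fraction, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contigs") <- attr(reads, "contigs")
  attr(out, "malformed") <- attr(reads, "malformed")
  out
}

#' Subsample reads to a target mean coverage
#'
#' Computes the sample's mean coverage (unfiltered: quality floors 0) and
#' keeps the fraction of reads needed to land at `target_cov` on average.
#'
#' @param reads Read data.frame.
#' @param reference A [mito_reference()].
#' @param target_cov Target mean coverage (default 2000).
#' @param seed Integer seed.
#' @return Subsampled reads; the applied fraction is stored in the
#'   `"fraction"` attribute.
#' @export
subsample_to_coverage <- function(reads, reference, target_cov = 2000,
                                  seed = MITOVAR_SUBSAMPLE_SEED) {
  cov <- mean_coverage(reads, reference, min_baseq = 0L, min_mapq = 0L)
  frac <- subsample_fraction(cov$mean, target_cov)
  out <- subsample_reads(reads, frac, seed)
  attr(out, "fraction") <- frac
  out
}
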