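## Bayesian SNV / heteroplasmy caller.
##
## Per reference position the model scores 4 homoplasmic hypotheses HOM(X)
## and up to 6 heteroplasmic hypotheses HET(M, m) -- one per unordered base
## pair with both bases observed, with the minor fraction fixed at the
## empirical fraction f = n_m / (n_M + n_m). The likelihood of an observed
## base b with Phred quality q (error probability e):
##   P(b | HOM X)      = 1 - e        if b == X, else e/3
##   P(b | HET M,m,f)  = (1-f) P(b|HOM M) + f P(b|HOM m)
## The prior splits mass (1 - theta_het) over HOM hypotheses in proportion
## to population allele frequencies, and theta_het equally over the
## candidate HET pairs. The maximum-posterior hypothesis decides the call.
##
## `posterior_genotypes()` is the readable single-column implementation;
## `call_snvs()` re-derives the same posteriors with matrix arithmetic over
## all positions at once (the two are cross-checked in the test suite).

#' Convert a Phred quality to an error probability
#'
#' Standard Phred definition e = 10^(-q/10), clamped to [1e-6, 0.75]: the
#' lower clamp stops a single miscalibrated Q60+ base from dominating a
#' likelihood, the upper keeps `1 - e` informative even for q = 0.
#'
#' @param q Phred score(s), non-negative.
#' @return Error probabilities in [1e-6, 0.75].
#' @export
phred_to_error <- function(q) {
  if (any(q < 0)) stop("Phred quality must be non-negative")
  pmin(pmax(10^(-q / 10), 1e-6), 0.75)
}

#' Extract one pileup column with its retained observations
#'
#' @param pileup A `mito_pileup`.
#' @param pos 1-based position.
#' @return List with `pos`, `ref_base`, `counts` (2 x 4 strand-by-base),
#'   `depth`, `mean_baseq` and `obs`, a data.frame of (base, qual, count)
#'   observation classes.
#' @export
pileup_column <- function(pileup, pos) {
  stopifnot(inherits(pileup, "mito_pileup"), pos >= 1L, pos <= length(pileup$depth))
  bq <- pileup$bq_counts[pos, , , drop = TRUE]
  if (is.null(dim(bq))) bq <- matrix(bq, nrow = 4L, dimnames = list(BASES, pileup$quals[1]))
  idx <- which(bq > 0, arr.ind = TRUE)
  obs <- data.frame(
    base = BASES[idx[, 1L]],
    qual = pileup$quals[idx[, 2L]],
    count = bq[idx],
    stringsAsFactors = FALSE
  )
  list(
    pos = pos,
    ref_base = substr(pileup$reference$sequence, pos, pos),
    counts = t(pileup$counts[pos, , ]),
    depth = pileup$depth[pos],
    mean_baseq = pileup$mean_baseq[pos],
    obs = obs
  )
}

#' Log-likelihood of a genotype hypothesis for one pileup column
#'
#' @param column A column from [pileup_column()].
#' @param hypothesis List with `kind` ("HOM" or "HET"), `major`, and for
#'   HET also `minor` and the minor fraction `f`.
#' @return Log-likelihood (base e).
#' @export
log_likelihood <- function(column, hypothesis) {
  obs <- column$obs
  if (!nrow(obs)) return(0)
  e <- phred_to_error(obs$qual)
  p_hom <- function(base) ifelse(obs$base == base, 1 - e, e / 3)
  p <- if (hypothesis$kind == "HOM") {
    p_hom(hypothesis$major)
  } else {
    stopifnot(hypothesis$major != hypothesis$minor,
              hypothesis$f > 0, hypothesis$f < 1)
    (1 - hypothesis$f) * p_hom(hypothesis$major) +
      hypothesis$f * p_hom(hypothesis$minor)
  }
  sum(obs$count * log(p))
}

## Candidate HET hypotheses for a column: every unordered base pair with
## both bases observed; major = the more frequent base (ties broken toward
## the reference base, then alphabetically); f = empirical minor fraction.
column_het_candidates <- function(nb, ref_base) {
  pairs <- utils::combn(4L, 2L)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    if (nb[i] > 0 && nb[j] > 0) {
      if (nb[i] > nb[j]) { M <- i; m <- j }
      else if (nb[j] > nb[i]) { M <- j; m <- i }
      else if (BASES[j] == ref_base) { M <- j; m <- i }
      else { M <- i; m <- j }
      out[[length(out) + 1L]] <- list(
        kind = "HET", major = BASES[M], minor = BASES[m],
        f = nb[m] / (nb[i] + nb[j])
      )
    }
  }
  out
}

#' Posterior probabilities of genotype hypotheses at one column
#'
#' With no data (depth 0) the posterior over the four homoplasmic
#' hypotheses equals the prior. Posteriors are computed in log space and
#' normalized to sum to 1.
#'
#' @param column A column from [pileup_column()].
#' @param priors A [mito_priors()].
#' @return data.frame with kind, major, minor, f, log_posterior (un-normalized)
#'   and posterior (normalized), sorted by decreasing posterior with ties
#'   broken toward reference-containing hypotheses.
#' @export
posterior_genotypes <- function(column, priors = mito_priors()) {
  pm <- prior_freqs_at(priors, column$pos)
  hyps <- lapply(BASES, function(b) list(kind = "HOM", major = b, minor = NA_character_, f = NA_real_))
  nb <- colSums(column$counts)
  if (column$depth > 0L) {
    hets <- column_het_candidates(nb, column$ref_base)
  } else {
    hets <- list()
  }
  n_het <- length(hets)
  log_prior <- c(
    log1p(-priors$theta_het) + log(pm),
    if (n_het) rep(log(priors$theta_het / n_het), n_het)
  )
  hyps <- c(hyps, hets)
  ll <- vapply(hyps, function(h) log_likelihood(column, h), numeric(1))
  lp <- ll + log_prior
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  out <- data.frame(
    kind = vapply(hyps, `[[`, character(1), "kind"),
    major = vapply(hyps, `[[`, character(1), "major"),
    minor = vapply(hyps, function(h) as.character(h$minor %||% NA), character(1)),
    f = vapply(hyps, function(h) as.numeric(h$f %||% NA), numeric(1)),
    log_posterior = lp,
    posterior = post,
    stringsAsFactors = FALSE
  )
  ref_pref <- (out$major == column$ref_base) |
    (!is.na(out$minor) & out$minor == column$ref_base)
  out[order(-out$posterior, -ref_pref, out$major, out$minor, na.last = TRUE), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

prior_freqs_at <- function(priors, pos) {
  if (!is.null(priors$table)) {
    hit <- match(pos, priors$table$pos)
    if (!is.na(hit)) {
      return(as.numeric(priors$table[hit, c("A", "C", "G", "T")]))
    }
  }
  rep(0.25, 4L)
}

#' Call homoplasmic and heteroplasmic SNVs from a pileup
#'
#' For each column with depth at least `min_depth`, the maximum-posterior
#' hypothesis is selected. A non-reference homoplasmic winner becomes a
#' homoplasmic call (VAF 1). A heteroplasmic winner becomes a heteroplasmy
#' call at the non-reference allele's level only when that level is at
#' least `min_vaf` and the minor allele is supported by at least
#' `min_minor_per_strand` observations on each strand; otherwise the column
#' falls back to the homoplasmic interpretation of the major allele.
#'
#' @param pileup A `mito_pileup`.
#' @param priors A [mito_priors()].
#' @param min_vaf Heteroplasmy detection floor (default 0.02).
#' @param min_minor_per_strand Minimum minor-allele observations per strand
#'   (default 2).
#' @param min_depth Minimum column depth to attempt a call (default 10).
#' @return A `mito_calls` data.frame: pos, ref, alt, type, vaf, depth,
#'   n_alt, alt_fwd, alt_rev, mean_baseq (alt-supporting), gt, filter, src.
#' @export
call_snvs <- function(pileup, priors = mito_priors(), min_vaf = 0.02,
                      min_minor_per_strand = 2L, min_depth = 10L) {
  stopifnot(inherits(pileup, "mito_pileup"))
  L <- length(pileup$depth)
  ref_code <- base_code(utf8ToInt(pileup$reference$sequence))
  depth <- pileup$depth
  nb <- pileup$counts[, , 1L] + pileup$counts[, , 2L]      # L x 4 totals
  quals <- pileup$quals
  e <- phred_to_error(quals)
  log_hit <- log(1 - e)
  log_miss <- log(e / 3)

  nq <- length(quals)
  Nq <- matrix(0, nrow = L, ncol = nq)                      # obs per qual level
  for (k in seq_len(nq)) Nq[, k] <- rowSums(pileup$bq_counts[, , k])

  ## HOM log-likelihoods
  ll <- matrix(0, nrow = L, ncol = 10L)
  for (x in 1:4) {
    acc <- numeric(L)
    for (k in seq_len(nq)) {
      nxk <- pileup$bq_counts[, x, k]
      acc <- acc + nxk * log_hit[k] + (Nq[, k] - nxk) * log_miss[k]
    }
    ll[, x] <- acc
  }

  ## HET log-likelihoods per unordered pair
  pairs <- utils::combn(4L, 2L)
  valid <- matrix(FALSE, nrow = L, ncol = 6L)
  major_code <- matrix(NA_integer_, nrow = L, ncol = 6L)
  f_mat <- matrix(NA_real_, nrow = L, ncol = 6L)
  for (p in 1:6) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    ni <- nb[, i]; nj <- nb[, j]
    v <- ni > 0L & nj > 0L
    valid[, p] <- v
    Mi <- ifelse(ni > nj, i, ifelse(nj > ni, j, ifelse(ref_code == j, j, i)))
    major_code[, p] <- Mi
    nmin <- pmin(ni, nj)
    ## on ties the minor count equals either; f = minor/(ni+nj)
    f <- ifelse(v, nmin / (ni + nj), NA_real_)
    ## tie (ni == nj) gives f = 0.5 regardless of major labelling
    f_mat[, p] <- f
    acc <- numeric(L)
    for (k in seq_len(nq)) {
      nik <- pileup$bq_counts[, i, k]
      njk <- pileup$bq_counts[, j, k]
      nMk <- ifelse(Mi == i, nik, njk)
      nmk <- ifelse(Mi == i, njk, nik)
      pM <- (1 - f) * exp(log_hit[k]) + f * exp(log_miss[k])
      pm <- (1 - f) * exp(log_miss[k]) + f * exp(log_hit[k])
      acc <- acc + ifelse(v,
        nMk * log(pM) + nmk * log(pm) + (Nq[, k] - nik - njk) * log_miss[k],
        0)
    }
    ll[, 4L + p] <- ifelse(v, acc, -Inf)
  }

  ## priors
  pm_hom <- prior_matrix(priors, L)
  n_het <- rowSums(valid)
  lp <- ll
  lp[, 1:4] <- lp[, 1:4] + log1p(-priors$theta_het) + log(pm_hom)
  for (p in 1:6) {
    lp[, 4L + p] <- lp[, 4L + p] +
      ifelse(valid[, p], log(priors$theta_het / pmax(n_het, 1L)), -Inf)
  }

  ## deterministic tie-break: prefer reference-containing hypotheses, then
  ## the fixed column order (HOM A..T, then pairs in lexicographic order)
  contains_ref <- matrix(FALSE, nrow = L, ncol = 10L)
  for (x in 1:4) contains_ref[, x] <- ref_code == x
  for (p in 1:6) {
    contains_ref[, 4L + p] <- ref_code == pairs[1L, p] | ref_code == pairs[2L, p]
  }
  tie_bias <- contains_ref * 1e-9 - matrix(rep(seq_len(10L) * 1e-12, each = L), nrow = L)
  best <- max.col(lp + tie_bias, ties.method = "first")

  callable <- which(depth >= min_depth)
  calls <- list()
  mean_bq_alt <- function(pos, code) {
    n <- as.numeric(pileup$bq_counts[pos, code, ])
    tot <- sum(n)
    if (tot == 0) return(pileup$mean_baseq[pos])
    sum(n * quals) / tot
  }
  emit <- function(pos, alt_code, vaf, gt) {
    data.frame(
      pos = pos, ref = BASES[ref_code[pos]], alt = BASES[alt_code],
      type = "SNV", vaf = vaf, depth = depth[pos],
      n_alt = nb[pos, alt_code],
      alt_fwd = pileup$counts[pos, alt_code, 1L],
      alt_rev = pileup$counts[pos, alt_code, 2L],
      mean_baseq = mean_bq_alt(pos, alt_code),
      gt = gt, filter = "PASS", src = "bayes-snv",
      stringsAsFactors = FALSE
    )
  }

  for (pos in callable) {
    b <- best[pos]
    rc <- ref_code[pos]
    if (rc == 0L) next  # N in reference: no call
    if (b <= 4L) {
      if (b != rc) calls[[length(calls) + 1L]] <- emit(pos, b, 1.0, "1/1")
      next
    }
    p <- b - 4L
    M <- major_code[pos, p]
    m <- setdiff(pairs[, p], M)
    f <- f_mat[pos, p]
    minor_ok <- pileup$counts[pos, m, 1L] >= min_minor_per_strand &&
      pileup$counts[pos, m, 2L] >= min_minor_per_strand
    if (M == rc) {
      lvl <- f
      if (lvl >= min_vaf && minor_ok) {
        calls[[length(calls) + 1L]] <- emit(pos, m, lvl, "0/1")
      }
      ## else fall back to HOM(ref): no call
    } else if (m == rc) {
      lvl <- 1 - f
      if (lvl >= min_vaf && minor_ok) {
        calls[[length(calls) + 1L]] <- emit(pos, M, lvl, "0/1")
      } else {
        calls[[length(calls) + 1L]] <- emit(pos, M, 1.0, "1/1")
      }
    } else {
      ## neither allele is the reference: the major is reported as a
      ## homoplasmic-style substitution, the minor as a heteroplasmy
      calls[[length(calls) + 1L]] <- emit(pos, M, 1 - f, "1/1")
      if (f >= min_vaf && minor_ok) {
        calls[[length(calls) + 1L]] <- emit(pos, m, f, "0/1")
      }
    }
  }

  out <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  rownames(out) <- NULL
  class(out) <- c("mito_calls", "data.frame")
  out
}

empty_calls <- function() {
  data.frame(
    pos = integer(0), ref = character(0), alt = character(0),
    type = character(0), vaf = numeric(0), depth = integer(0),
    n_alt = integer(0), alt_fwd = integer(0), alt_rev = integer(0),
    mean_baseq = numeric(0), gt = character(0), filter = character(0),
    src = character(0), stringsAsFactors = FALSE
  )
}

#' @export
print.mito_calls <- function(x, ...) {
  cat(sprintf(
    "<mito_calls> %d call(s): %d SNV, %d INS, %d DEL (%d flagged)\n",
    nrow(x), sum(x$type == "SNV"), sum(x$type == "INS"), sum(x$type == "DEL"),
    sum(x$filter != "PASS")
  ))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more row(s)\n")
  invisible(x)
}

#' @method summary mito_calls
#' @export
summary.mito_calls <- function(object, ...) {
  het <- object$vaf < 1
  structure(list(
    n = nrow(object),
    by_type = table(object$type),
    n_heteroplasmic = sum(het),
    vaf_range = if (any(het)) range(object$vaf[het]) else c(NA_real_, NA_real_),
    n_flagged = sum(object$filter != "PASS")
  ), class = "summary.mito_calls")
}

#' @export
print.summary.mito_calls <- function(x, ...) {
  cat(sprintf("%d variant call(s); %d heteroplasmic, %d flagged\n",
              x$n, x$n_heteroplasmic, x$n_flagged))
  print(x$by_type)
  if (!is.na(x$vaf_range[1])) {
    cat(sprintf("heteroplasmy VAF range: %.4f - %.4f\n",
                x$vaf_range[1], x$vaf_range[2]))
  }
  invisible(x)
}
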