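test_that("minimal alt-read count matches hand-computed binomial tails", {
  # p = 0: any alt read is significant
  expect_equal(min_alt_reads(50, 0, 0.05), 1L)
  expect_equal(min_alt_reads(1, 0, 0.01), 1L)

  # N=10, p=0.5: P(X>=9) = 11/1024 < 0.05 but P(X>=8) = 56/1024 >= 0.05
  expect_equal(min_alt_reads(10, 0.5, 0.05), 9L)

  # N=1000, Q30 (p=0.001): 4 alt reads needed, min VAF 0.004
  expect_equal(min_alt_reads(1000, 0.001, 0.05), 4L)
  r <- min_trusted_vaf(1000, 30, 0.05)
  expect_equal(r$k_star, 4L)
  expect_equal(r$min_vaf, 0.004)

  # alpha near 1: a single read suffices
  expect_equal(min_alt_reads(100, 0.001, 0.999), 1L)

  # unachievable at this depth: N+1 with the achievable flag down
  expect_equal(min_alt_reads(1, 0.9, 0.05), 2L)
  expect_false(min_trusted_vaf(1, 0, 0.05)$achievable)  # Q0 -> p = 0.75
  expect_false(min_trusted_vaf(0, 30, 0.05)$achievable)
})

test_that("stable tail computation matches brute-force summation over a grid", {
  for (N in c(1, 10, 100, 1000, 10000)) {
    for (p in c(0, 1e-4, 1e-3, 1e-2, 0.1, 0.5)) {
      for (alpha in c(0.01, 0.05)) {
        got <- min_alt_reads(N, p, alpha)
        want <- k_star_bruteforce(N, p, alpha)
        expect_equal(got, want,
                     info = sprintf("N=%d p=%g alpha=%g", N, p, alpha))
        if (got <= N && p > 0) {
          expect_lt(abs(tail_bruteforce(got, N, p) -
                        pbinom(got - 1, N, p, lower.tail = FALSE)) /
                      tail_bruteforce(got, N, p), 1e-9)
        }
      }
    }
  }
})

test_that("k_star is monotone in error rate and significance level", {
  N <- 2000
  ps <- c(1e-4, 1e-3, 1e-2, 0.05, 0.1)
  ks <- vapply(ps, function(p) min_alt_reads(N, p, 0.05), integer(1))
  expect_true(all(diff(ks) >= 0))  # non-decreasing in p

  alphas <- c(0.001, 0.01, 0.05, 0.2)
  ks <- vapply(alphas, function(a) min_alt_reads(N, 0.001, a), integer(1))
  expect_true(all(diff(ks) <= 0))  # non-increasing in alpha

  # min VAF vanishes as depth grows with p fixed
  mv <- vapply(c(100, 1000, 10000), function(n) min_trusted_vaf(n, 30, 0.05)$min_vaf,
               numeric(1))
  expect_true(all(diff(mv) < 0))
})

test_that("flagging marks under-supported calls without removing any", {
  calls <- data.frame(
    pos = c(10L, 20L, 30L),
    ref = "A", alt = "G", type = "SNV",
    vaf = c(0.003, 0.01, 1.0),
    depth = c(1000L, 1000L, 1000L),
    n_alt = c(3L, 10L, 1000L),
    alt_fwd = c(2L, 5L, 500L), alt_rev = c(1L, 5L, 500L),
    mean_baseq = 30, gt = c("0/1", "0/1", "1/1"),
    filter = "PASS", src = "bayes-snv",
    stringsAsFactors = FALSE
  )
  class(calls) <- c("mito_calls", "data.frame")
  out <- flag_calls(calls, alpha = 0.05)
  expect_equal(nrow(out), nrow(calls))                   # flag, never filter
  expect_equal(out$filter, c("low_vaf_for_coverage", "PASS", "PASS"))
  expect_equal(out$k_star, rep(4L, 3))                   # N=1000, Q30 oracle

  # a homoplasmic call (alt == depth) is never flagged at achievable k_star
  hom <- calls[3, , drop = FALSE]
  class(hom) <- c("mito_calls", "data.frame")
  for (a in c(0.001, 0.05, 0.2)) {
    expect_equal(flag_calls(hom, alpha = a)$filter, "PASS")
  }
})

test_that("mean detectable VAF reduces correctly and is monotone in coverage", {
  ref <- mito_reference("chrM", strrep("ACGT", 25))
  # uniform depth 1000 at Q30 everywhere: equals the single-position value
  reads <- make_reads(
    pos = rep(1L, 1000),
    seq = rep(ref$sequence, 1000),
    flag = rep(c(0L, 16L), 500)
  )
  pl <- build_pileup(reads, ref)
  expect_true(all(pl$depth == 1000L))
  expect_equal(sample_mean_detectable_vaf(pl, 0.05), 0.004)

  # doubling coverage does not increase the mean detectable VAF
  ref2 <- simulate_reference(1000, seed = 181)
  lo <- build_pileup(simulate_reads(ref2, NULL, coverage = 100, seed = 182), ref2)
  hi <- build_pileup(simulate_reads(ref2, NULL, coverage = 200, seed = 183), ref2)
  expect_lte(sample_mean_detectable_vaf(hi, 0.05),
             sample_mean_detectable_vaf(lo, 0.05))

  # no coverage at all: undefined
  empty <- build_pileup(make_reads(integer(0), character(0)), ref2)
  expect_true(is.na(sample_mean_detectable_vaf(empty)))
})

test_that("a deep Q30 sample reaches the 2% detection floor", {
  ref <- simulate_reference(2000, seed = 191)
  reads <- simulate_reads(ref, NULL, coverage = 2000, seed = 192)
  pl <- build_pileup(reads, ref)
  expect_lt(sample_mean_detectable_vaf(pl, 0.05), 0.02)
})
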