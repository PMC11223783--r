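test_that("Phred conversion follows the standard definition with clamping", {
  expect_equal(phred_to_error(30), 0.001)
  expect_equal(phred_to_error(10), 0.1)
  expect_equal(phred_to_error(0), 0.75)    # clamped from 1.0
  expect_equal(phred_to_error(90), 1e-6)   # clamped from 1e-9
  expect_error(phred_to_error(-1), "non-negative")
})

# a pileup column with the given base string observed at Q30 on both strands
column_from_bases <- function(bases, ref = "ACGTACGT", pos = 1L) {
  n <- nchar(bases)
  reference <- mito_reference("chrM", ref)
  reads <- make_reads(
    pos = rep(pos, n),
    seq = strsplit(bases, "")[[1]],
    flag = rep(c(0L, 16L), length.out = n)
  )
  pileup_column(build_pileup(reads, reference), pos)
}

test_that("log-likelihoods follow the Phred mixture formulas", {
  col <- column_from_bases("AA")
  expect_equal(log_likelihood(col, list(kind = "HOM", major = "A")),
               2 * log(0.999))
  expect_equal(log_likelihood(col, list(kind = "HOM", major = "C")),
               2 * log(0.001 / 3))

  col <- column_from_bases("AG")
  het <- log_likelihood(col, list(kind = "HET", major = "A", minor = "G", f = 0.5))
  expect_equal(het, 2 * log(0.5 * 0.999 + 0.5 * 0.001 / 3))
  # the balanced heteroplasmic hypothesis beats both homoplasmic ones
  expect_gt(het, log_likelihood(col, list(kind = "HOM", major = "A")))
  expect_gt(het, log_likelihood(col, list(kind = "HOM", major = "G")))
})

test_that("posteriors normalize, favor the data, and reduce to the prior without data", {
  # no data: posterior equals the prior over homoplasmic hypotheses
  ref <- mito_reference("chrM", "ACGT")
  pl <- build_pileup(make_reads(integer(0), character(0)), ref)
  post <- posterior_genotypes(pileup_column(pl, 2L))
  expect_equal(sum(post$posterior), 1, tolerance = 1e-12)
  expect_true(all(post$kind == "HOM"))
  expect_equal(post$posterior, rep(0.25, 4))

  # overwhelming homoplasmic signal
  col <- column_from_bases(strrep("A", 100))
  post <- posterior_genotypes(col)
  expect_equal(sum(post$posterior), 1, tolerance = 1e-12)
  expect_equal(post$kind[1], "HOM")
  expect_equal(post$major[1], "A")
  expect_gt(post$posterior[1], 0.999)

  # a 5% minor allele wins as heteroplasmy with the empirical fraction
  col <- column_from_bases(paste0(strrep("A", 95), strrep("G", 5)))
  post <- posterior_genotypes(col)
  expect_equal(post$kind[1], "HET")
  expect_setequal(c(post$major[1], post$minor[1]), c("A", "G"))
  expect_equal(post$f[1], 0.05)
})

test_that("the vectorized caller agrees with the per-column posterior model", {
  ref <- simulate_reference(1500, seed = 91)
  truth <- spike_variants(ref, n_snv = 6, n_indel = 0, seed = 92,
                          vafs = c(0.05, 0.2, 0.5))
  reads <- simulate_reads(ref, truth, coverage = 200, seed = 93)
  pl <- build_pileup(reads, ref)
  calls <- call_snvs(pl)

  # at every truth position the per-column argmax implies the same call
  for (p in truth$pos) {
    post <- posterior_genotypes(pileup_column(pl, p))
    top <- post[1, ]
    hit <- calls[calls$pos == p, ]
    expect_equal(nrow(hit), 1L)
    expect_equal(top$kind, "HET")
    expected_vaf <- if (top$major == substr(ref$sequence, p, p)) top$f else 1 - top$f
    expect_equal(hit$vaf, expected_vaf)
  }
  # and at a panel of non-variant positions the argmax is HOM(ref)
  set.seed(94)
  for (p in sample(setdiff(which(pl$depth > 50), truth$pos), 25)) {
    post <- posterior_genotypes(pileup_column(pl, p))
    expect_equal(post$kind[1], "HOM")
    expect_equal(post$major[1], substr(ref$sequence, p, p))
  }
})

test_that("posterior normalization holds across all columns of a noisy sample", {
  ref <- simulate_reference(400, seed = 101)
  reads <- simulate_reads(ref, NULL, coverage = 80, error_rate = 0.01, seed = 102)
  pl <- build_pileup(reads, ref)
  sums <- vapply(seq_len(ref$length), function(p) {
    sum(posterior_genotypes(pileup_column(pl, p))$posterior)
  }, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("call gates enforce the VAF floor, strand support and depth", {
  ref <- mito_reference("chrM", strrep("ACGT", 100))

  # 99 A / 1 G at a reference-A position: 1% is below the 2% floor
  reads <- make_reads(pos = rep(1L, 100),
                      seq = c(rep("A", 99), "G"),
                      flag = rep(c(0L, 16L), 50))
  calls <- call_snvs(build_pileup(reads, ref))
  expect_equal(nrow(calls), 0L)

  # homoplasmic disagreement with the reference is always called
  reads <- make_reads(pos = rep(2L, 50), seq = rep("A", 50),
                      flag = rep(c(0L, 16L), 25))  # ref at 2 is C
  calls <- call_snvs(build_pileup(reads, ref))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$ref, "C")
  expect_equal(calls$alt, "A")
  expect_equal(calls$vaf, 1.0)
  expect_equal(calls$gt, "1/1")

  # 10% minor allele but all on one strand: strand gate refuses it
  reads <- make_reads(pos = rep(1L, 100),
                      seq = c(rep("A", 90), rep("G", 10)),
                      flag = c(rep(c(0L, 16L), 45), rep(0L, 10)))
  calls <- call_snvs(build_pileup(reads, ref))
  expect_equal(nrow(calls), 0L)

  # same 10% with balanced strands is called
  reads <- make_reads(pos = rep(1L, 100),
                      seq = c(rep("A", 90), rep("G", 10)),
                      flag = c(rep(c(0L, 16L), 45), rep(c(0L, 16L), 5)))
  calls <- call_snvs(build_pileup(reads, ref))
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$alt, "G")
  expect_equal(calls$vaf, 0.10)

  # below min_depth nothing is attempted
  reads <- make_reads(pos = rep(1L, 5), seq = rep("G", 5))
  expect_equal(nrow(call_snvs(build_pileup(reads, ref))), 0L)
})

test_that("raising the VAF floor never increases the number of calls", {
  ref <- simulate_reference(2500, seed = 111)
  truth <- spike_variants(ref, n_snv = 10, n_indel = 0, seed = 112)
  reads <- simulate_reads(ref, truth, coverage = 500, seed = 113)
  pl <- build_pileup(reads, ref)
  n_calls <- vapply(c(0.01, 0.02, 0.05, 0.1, 0.3, 0.6),
                    function(v) nrow(call_snvs(pl, min_vaf = v)), numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("error-free reference-matching reads yield zero calls", {
  ref <- simulate_reference(2000, seed = 121)
  reads <- simulate_reads(ref, NULL, coverage = 150, error_rate = 0, seed = 122)
  pl <- build_pileup(reads, ref)
  expect_equal(nrow(call_snvs(pl)), 0L)
  expect_equal(nrow(call_indels(pl)), 0L)
})

test_that("a position-specific prior table shifts borderline posteriors", {
  prior_file <- system.file("extdata", "synthetic_priors.tsv", package = "mitovar")
  skip_if(prior_file == "")
  priors <- read_prior_table(prior_file)
  expect_s3_class(priors, "mito_priors")
  expect_true(all(abs(rowSums(priors$table[, c("A", "C", "G", "T")]) - 1) < 1e-8))

  # at a listed position the favored base needs less evidence than a
  # disfavored one
  tab <- priors$table
  p73 <- as.numeric(tab[tab$pos == 73, c("A", "C", "G", "T")])
  expect_gt(p73[3], p73[2])  # G favored over C at this position
})
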