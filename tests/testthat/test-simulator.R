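test_that("simulated references are seeded, sized and roughly uniform", {
  ref <- simulate_reference(16569, seed = 241)
  expect_equal(ref$length, 16569L)
  expect_equal(ref$name, "chrM")
  expect_identical(simulate_reference(16569, seed = 241)$sequence, ref$sequence)
  expect_false(identical(simulate_reference(16569, seed = 242)$sequence, ref$sequence))
  comp <- table(strsplit(ref$sequence, "")[[1]]) / ref$length
  expect_true(all(comp > 0.24 & comp < 0.26))
})

test_that("spiked truth sets have the requested composition and stay normalized", {
  ref <- simulate_reference(16569, seed = 251)
  truth <- spike_variants(ref, n_snv = 35, n_indel = 8, seed = 252)
  expect_equal(nrow(truth), 43L)
  expect_equal(sum(truth$type == "SNV"), 35L)
  expect_equal(sum(truth$type %in% c("INS", "DEL")), 8L)
  expect_true(all(truth$target_vaf >= 0.02 & truth$target_vaf <= 0.5))
  expect_true(all(diff(truth$pos) >= 10L))

  # every truth record is a fixpoint of the normalizer
  for (i in seq_len(nrow(truth))) {
    n <- normalize_variant(truth$pos[i], truth$ref[i], truth$alt[i], ref)
    expect_equal(n$pos, truth$pos[i])
    expect_equal(n$ref, truth$ref[i])
    expect_equal(n$alt, truth$alt[i])
  }

  empty <- spike_variants(ref, n_snv = 0, n_indel = 0, seed = 253)
  expect_equal(nrow(empty), 0L)

  tiny <- mito_reference("chrM", strrep("ACGT", 15))
  expect_error(spike_variants(tiny, n_snv = 30, n_indel = 10, seed = 254),
               "cannot place")
})

test_that("read simulation hits nominal coverage and target allele fractions", {
  ref <- simulate_reference(4000, seed = 261)
  truth <- spike_variants(ref, n_snv = 1, n_indel = 0, vafs = 0.5, seed = 262)
  reads <- simulate_reads(ref, truth, coverage = 2000, seed = 263)

  pl <- build_pileup(reads, ref, min_baseq = 0L, min_mapq = 0L)
  expect_lt(abs(mean(pl$depth) - 2000) / 2000, 0.05)

  p <- truth$pos
  altc <- pl$counts[p, truth$alt, "fwd"] + pl$counts[p, truth$alt, "rev"]
  expect_lt(abs(altc / pl$depth[p] - 0.5), 0.03)

  # determinism: the same seed reproduces the identical read set
  again <- simulate_reads(ref, truth, coverage = 2000, seed = 263)
  expect_identical(again$seq, reads$seq)
  expect_identical(again$pos, reads$pos)
})

test_that("evaluation scores exact matches and splits by variant class", {
  ref <- simulate_reference(3000, seed = 271)
  truth <- spike_variants(ref, n_snv = 6, n_indel = 3, seed = 272)
  as_calls <- function(t) {
    out <- data.frame(
      pos = t$pos, ref = t$ref, alt = t$alt, type = t$type,
      vaf = t$target_vaf, depth = 100L, n_alt = 10L, alt_fwd = 5L,
      alt_rev = 5L, mean_baseq = 30, gt = "0/1", filter = "PASS",
      src = "test", stringsAsFactors = FALSE
    )
    class(out) <- c("mito_calls", "data.frame")
    out
  }

  perfect <- evaluate_calls(as_calls(truth), truth)
  expect_equal(perfect$all, list(tp = 9, fp = 0, fn = 0, all_sites = 9))

  none <- evaluate_calls(as_calls(truth)[0, ], truth)
  expect_equal(none$all$fn, 9)
  expect_equal(none$all$all_sites, 0)

  # an SNV-only caller misses exactly the indels
  snv_only <- evaluate_calls(as_calls(truth[truth$type == "SNV", ]), truth)
  expect_equal(snv_only$indel$fn, 3)
  expect_equal(snv_only$snv$fn, 0)
  expect_equal(snv_only$all$fn, 3)

  # a shifted call is both a false positive and leaves a false negative
  shifted <- as_calls(truth)
  shifted$pos[1] <- shifted$pos[1] + 1L
  ev <- evaluate_calls(shifted, truth)
  expect_equal(ev$all$fp, 1)
  expect_equal(ev$all$fn, 1)
})

test_that("called VAF tracks target VAF with slope near one at depth", {
  ref <- simulate_reference(16569, seed = 281)
  truth <- spike_variants(ref, n_snv = 40, n_indel = 0, seed = 282)
  reads <- simulate_reads(ref, truth, coverage = 2000, seed = 283)
  calls <- call_snvs(build_pileup(reads, ref))
  m <- merge(as.data.frame(calls), as.data.frame(truth),
             by = c("pos", "ref", "alt"))
  expect_equal(nrow(m), 40L)
  fit <- lm(vaf ~ target_vaf, data = m)
  expect_gt(coef(fit)[["target_vaf"]], 0.9)
  expect_lt(coef(fit)[["target_vaf"]], 1.1)
})
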