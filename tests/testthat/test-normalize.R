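test_that("multiallelic records split into per-allele biallelic records", {
  rec <- data.frame(
    chrom = "chrM", pos = 100L, id = ".", ref = "A", alt = "G,T",
    qual = NA_real_, filter = "PASS", info = "SRC=x", gt = "0/1",
    dp = 500L, af = "0.2,0.05", stringsAsFactors = FALSE
  )
  out <- split_multiallelic(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$alt, c("G", "T"))
  expect_equal(out$af, c(0.2, 0.05))
  expect_equal(out$pos, c(100L, 100L))

  # biallelic input is returned unchanged
  bi <- rec; bi$alt <- "G"; bi$af <- 0.2
  expect_identical(split_multiallelic(bi), bi)

  # mixed SNV + insertion alleles get their types by allele length
  mix <- rec; mix$alt <- "G,AT"
  out <- split_multiallelic(mix)
  expect_equal(allele_type(out$ref, out$alt), c("SNV", "INS"))
})

test_that("left alignment matches hand-worked cases", {
  ref <- mito_reference("chrM", "ATTTTC")
  # 1-bp deletion in the T homopolymer shifts all the way left
  out <- normalize_variant(4L, "TT", "T", ref)
  expect_equal(out[c("pos", "ref", "alt")], list(pos = 1L, ref = "AT", alt = "A"))
  expect_equal(out$type, "DEL")

  # SNVs pass through unchanged
  out <- normalize_variant(3L, "T", "G", ref)
  expect_equal(out[c("pos", "ref", "alt")], list(pos = 3L, ref = "T", alt = "G"))

  # trimming a shared trailing base can reduce an MNP-looking record to an SNV
  ref2 <- mito_reference("chrM", "AACGT")
  out <- normalize_variant(2L, "AC", "GC", ref2)
  expect_equal(out[c("pos", "ref", "alt")], list(pos = 2L, ref = "A", alt = "G"))
  expect_equal(out$type, "SNV")

  # insertion in a homopolymer left-aligns too
  ref3 <- mito_reference("chrM", "AGGGC")
  out <- normalize_variant(4L, "G", "GG", ref3)
  expect_equal(out[c("pos", "ref", "alt")], list(pos = 1L, ref = "A", alt = "AG"))

  # a deletion pinned at the contig start cannot left-extend
  ref4 <- mito_reference("chrM", "TTTTA")
  expect_error(normalize_variant(1L, "TT", "T", ref4), "left-extend")
})

test_that("normalization is idempotent and agrees with the enumeration oracle", {
  set.seed(161)
  n_cases <- 300L
  for (i in seq_len(n_cases)) {
    ref <- simulate_reference(60L, seed = 161000L + i)
    rec <- random_indel_record(ref)
    got <- normalize_variant(rec$pos, rec$ref, rec$alt, ref)
    want <- normalize_oracle(ref$sequence, rec$pos, rec$ref, rec$alt)
    expect_equal(got$pos, want$pos, info = sprintf("case %d", i))
    expect_equal(got$ref, want$ref, info = sprintf("case %d", i))
    expect_equal(got$alt, want$alt, info = sprintf("case %d", i))
    # idempotence
    again <- normalize_variant(got$pos, got$ref, got$alt, ref)
    expect_identical(again[c("pos", "ref", "alt")], got[c("pos", "ref", "alt")])
  }
})

test_that("fusion merge keeps indels on positional conflicts and SNVs elsewhere", {
  ref <- simulate_reference(500, seed = 171)
  snv_call <- function(pos, alt) {
    out <- data.frame(
      pos = pos, ref = ref_bases(ref, pos), alt = alt, type = "SNV",
      vaf = 0.1, depth = 100L, n_alt = 10L, alt_fwd = 5L, alt_rev = 5L,
      mean_baseq = 30, gt = "0/1", filter = "PASS", src = "bayes-snv",
      stringsAsFactors = FALSE
    )
    class(out) <- c("mito_calls", "data.frame")
    out
  }
  indel_call <- function(pos) {
    anchor <- ref_bases(ref, pos)
    nxt <- ref_bases(ref, pos + 1L)
    alt_ins <- setdiff(c("A", "C", "G", "T"), c(nxt, anchor))[1]
    out <- data.frame(
      pos = pos, ref = anchor, alt = paste0(anchor, alt_ins), type = "INS",
      vaf = 0.2, depth = 100L, n_alt = 20L, alt_fwd = 10L, alt_rev = 10L,
      mean_baseq = 30, gt = "0/1", filter = "PASS", src = "indel-standin",
      stringsAsFactors = FALSE
    )
    class(out) <- c("mito_calls", "data.frame")
    out
  }
  a <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

  snvs <- rbind(snv_call(100L, a(ref_bases(ref, 100L))),
                snv_call(200L, a(ref_bases(ref, 200L))))
  class(snvs) <- c("mito_calls", "data.frame")
  indels <- indel_call(100L)

  merged <- merge_fusion(snvs, indels, ref)
  expect_equal(nrow(merged), 2L)
  expect_equal(merged$type[merged$pos == 100L], "INS")  # indel wins at 100
  expect_equal(merged$type[merged$pos == 200L], "SNV")  # untouched SNV kept

  # an SNV-type record in the indel caller's output is discarded
  stray <- snv_call(300L, a(ref_bases(ref, 300L)))
  stray$src <- "indel-standin"
  both <- rbind(indels, stray)
  class(both) <- c("mito_calls", "data.frame")
  merged <- merge_fusion(snvs, both, ref)
  expect_false(300L %in% merged$pos)

  # empty indel set returns exactly the SNV set
  empty <- indels[0, , drop = FALSE]
  merged <- merge_fusion(snvs, empty, ref)
  expect_equal(as.data.frame(merged)[, c("pos", "ref", "alt")],
               as.data.frame(snvs)[, c("pos", "ref", "alt")])

  # duplicates collapse and output stays position-sorted
  dup <- rbind(snvs, snvs[1, ])
  class(dup) <- c("mito_calls", "data.frame")
  merged <- merge_fusion(dup, indels, ref)
  expect_equal(anyDuplicated(merged[, c("pos", "ref", "alt")]), 0L)
  expect_false(is.unsorted(merged$pos))

  # unnormalized input is rejected
  bad <- snvs
  bad$ref[1] <- paste0(bad$ref[1], ref_bases(ref, bad$pos[1] + 1L))
  bad$alt[1] <- paste0(bad$alt[1], ref_bases(ref, bad$pos[1] + 1L))
  expect_error(merge_fusion(bad, indels, ref), "unnormalized")
})
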