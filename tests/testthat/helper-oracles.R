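# Shared fixtures and independent oracles used across the suite.

# Construct an aligned-read data.frame by hand.
make_reads <- function(pos, seq, cigar = paste0(nchar(seq), "M"),
                       qual = strrep("?", nchar(seq)),  # "?" = Phred 30
                       flag = 0L, mapq = 60L, rname = "chrM",
                       qname = sprintf("r%03d", seq_along(pos))) {
  n <- length(pos)
  df <- data.frame(
    qname = rep_len(qname, n), flag = rep_len(as.integer(flag), n),
    rname = rep_len(rname, n), pos = as.integer(pos),
    mapq = rep_len(as.integer(mapq), n), cigar = rep_len(cigar, n),
    seq = rep_len(seq, n), qual = rep_len(qual, n),
    stringsAsFactors = FALSE
  )
  attr(df, "contigs") <- unique(rname)
  attr(df, "malformed") <- 0L
  df
}

# Brute-force binomial upper tail P(X >= k) by direct summation of the
# probability mass function -- the independent check for min_alt_reads().
tail_bruteforce <- function(k, N, p) {
  if (k > N) return(0)
  sum(stats::dbinom(seq.int(k, N), N, p))
}

k_star_bruteforce <- function(N, p, alpha) {
  for (k in seq_len(N)) {
    if (tail_bruteforce(k, N, p) < alpha) return(k)
  }
  N + 1L
}

# Enumeration oracle for indel normalization: two representations are
# equivalent iff they produce the same edited sequence; the canonical form
# is the most parsimonious (minimal total allele length -- any
# representation can be padded with shared flanking bases, so length comes
# first) and, among those, the left-most.
apply_record <- function(refseq, pos, ref, alt) {
  stopifnot(substr(refseq, pos, pos + nchar(ref) - 1L) == ref)
  paste0(
    substr(refseq, 1L, pos - 1L), alt,
    substr(refseq, pos + nchar(ref), nchar(refseq))
  )
}

normalize_oracle <- function(refseq, pos, ref, alt, max_allele = 25L) {
  target <- apply_record(refseq, pos, ref, alt)
  L <- nchar(refseq)
  best <- NULL
  for (p in seq_len(L)) {
    for (rlen in 1:max_allele) {
      if (p + rlen - 1L > L) break
      alen <- nchar(target) - (p - 1L) - (L - (p + rlen - 1L))
      if (alen < 1L || alen > max_allele) next
      r <- substr(refseq, p, p + rlen - 1L)
      a <- substr(target, p, p + alen - 1L)
      if (apply_record(refseq, p, r, a) == target) {
        cand <- list(pos = p, ref = r, alt = a)
        cand_len <- nchar(r) + nchar(a)
        best_len <- if (is.null(best)) Inf else nchar(best$ref) + nchar(best$alt)
        if (cand_len < best_len ||
            (cand_len == best_len && cand$pos < best$pos)) {
          best <- cand
        }
      }
    }
  }
  best
}

# Random redundant representation of an indel event for property tests:
# start from a simple insertion/deletion and pad it with shared flanking
# bases so the normalizer has work to do.
random_indel_record <- function(reference) {
  L <- reference$length
  kind <- sample(c("INS", "DEL"), 1L)
  len <- sample.int(4L, 1L)
  pos <- sample(seq.int(6L, L - len - 6L), 1L)
  anchor <- substr(reference$sequence, pos, pos)
  if (kind == "INS") {
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    rec <- list(pos = pos, ref = anchor, alt = paste0(anchor, ins))
  } else {
    rec <- list(
      pos = pos,
      ref = substr(reference$sequence, pos, pos + len),
      alt = anchor
    )
  }
  # pad with up to 3 shared trailing reference bases
  n_pad <- sample(0:3, 1L)
  if (n_pad > 0L) {
    tail_start <- rec$pos + nchar(rec$ref)
    pad <- substr(reference$sequence, tail_start, tail_start + n_pad - 1L)
    rec$ref <- paste0(rec$ref, pad)
    rec$alt <- paste0(rec$alt, pad)
  }
  # optionally prepend a shared leading base
  if (sample(c(TRUE, FALSE), 1L) && rec$pos > 1L) {
    b <- substr(reference$sequence, rec$pos - 1L, rec$pos - 1L)
    rec$pos <- rec$pos - 1L
    rec$ref <- paste0(b, rec$ref)
    rec$alt <- paste0(b, rec$alt)
  }
  rec
}
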