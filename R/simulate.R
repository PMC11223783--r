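## Seeded read simulator: generates a reference, spikes a truth set of
## heteroplasmic SNVs and short indels at chosen allele fractions, and
## emits aligned reads with Phred-driven sequencing errors. Every read
## independently carries each truth variant it fully overlaps with
## probability equal to the variant's target VAF, so observed allele
## fractions are binomial around the target. One seed fixes the entire
## dataset.

## Evaluate an expression under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a random mitochondrial-sized reference
#'
#' @param length Contig length in bp (default 16569, the size of the
#'   standard human mtDNA reference).
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param name Contig name (default "chrM").
#' @return A [mito_reference()].
#' @export
simulate_reference <- function(length = 16569L, seed = 1L, name = "chrM") {
  stopifnot(length > 0)
  seq <- with_seed(seed, paste(sample(BASES, length, replace = TRUE), collapse = ""))
  mito_reference(name, seq)
}

#' Spike a truth set of heteroplasmic variants into a reference
#'
#' Draws variant positions at least `min_spacing` bp apart, assigns SNVs a
#' random non-reference base and indels a random 1-5 bp inserted/deleted
#' sequence, and draws target VAFs uniformly from `[vaf_min, vaf_max]`.
#' Every emitted record is normalized (left-aligned, parsimonious), so the
#' truth set is directly comparable to normalized calls.
#'
#' @param reference A [mito_reference()].
#' @param n_snv Number of SNVs (default 35).
#' @param n_indel Number of indels (default 8; insertions and deletions
#'   chosen at random).
#' @param vaf_min,vaf_max Target VAF range (defaults 0.02 and 0.5).
#' @param vafs Optional explicit VAF vector, recycled across variants in
#'   placement order; overrides the uniform draw.
#' @param min_spacing Minimum distance between variant positions (bp).
#' @param indel_max_len Maximum indel length (default 5).
#' @param seed Integer seed.
#' @return A `mito_truth` data.frame: pos, ref, alt, type, target_vaf,
#'   sorted by position.
#' @export
spike_variants <- function(reference, n_snv = 35L, n_indel = 8L,
                           vaf_min = 0.02, vaf_max = 0.5, vafs = NULL,
                           min_spacing = 10L, indel_max_len = 5L, seed = 1L) {
  stopifnot(n_snv >= 0, n_indel >= 0)
  L <- reference$length
  n_total <- n_snv + n_indel
  if (n_total == 0L) {
    out <- data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      type = character(0), target_vaf = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("mito_truth", "data.frame")
    return(out)
  }
  if (n_total * (min_spacing + indel_max_len) > L - 20L) {
    stop("cannot place ", n_total, " variants with spacing ", min_spacing,
         " on a ", L, " bp reference")
  }
  guard <- min_spacing + indel_max_len
  out <- with_seed(seed, {
    kinds <- sample(c(rep("SNV", n_snv),
                      sample(c("INS", "DEL"), n_indel, replace = TRUE)))
    taken <- integer(0)
    rows <- vector("list", n_total)
    tries <- 0L
    i <- 1L
    while (i <= n_total) {
      tries <- tries + 1L
      if (tries > 1000L * n_total) stop("variant placement did not converge")
      pos <- sample((guard + 1L):(L - guard), 1L)
      kind <- kinds[i]
      if (kind == "SNV") {
        rb <- ref_bases(reference, pos)
        ab <- sample(setdiff(BASES, rb), 1L)
        rec <- list(pos = pos, ref = rb, alt = ab, type = "SNV")
      } else if (kind == "INS") {
        len <- sample.int(indel_max_len, 1L)
        ins <- paste(sample(BASES, len, replace = TRUE), collapse = "")
        anchor <- ref_bases(reference, pos)
        rec <- normalize_variant(pos, anchor, paste0(anchor, ins), reference)
      } else {
        len <- sample.int(indel_max_len, 1L)
        anchor <- ref_bases(reference, pos - 1L)
        rec <- normalize_variant(pos - 1L,
                                 paste0(anchor, ref_bases(reference, pos, len)),
                                 anchor, reference)
      }
      span <- rec$pos + nchar(rec$ref) - 1L
      if (rec$pos <= guard ||
          any(abs(taken - rec$pos) < min_spacing) ||
          any(abs(taken - span) < min_spacing)) {
        next
      }
      taken <- c(taken, rec$pos, span)
      rows[[i]] <- data.frame(
        pos = rec$pos, ref = rec$ref, alt = rec$alt, type = rec$type,
        target_vaf = if (is.null(vafs)) stats::runif(1L, vaf_min, vaf_max)
                     else vafs[(i - 1L) %% length(vafs) + 1L],
        stringsAsFactors = FALSE
      )
      i <- i + 1L
    }
    do.call(rbind, rows)
  })
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mito_truth", "data.frame")
  out
}

#' Simulate aligned reads over a reference with spiked variants
#'
#' Reads of fixed length are placed uniformly on the (linear) reference,
#' assigned a random strand, and independently carry each truth variant
#' they fully overlap with probability `target_vaf`. Indels are realized in
#' the read sequence and CIGAR (reads stay "pre-aligned" by construction).
#' Sequencing errors are injected per base with probability
#' `phred_to_error(base_qual)`, substituting uniformly among the other
#' three bases; reported qualities stay at `base_qual`, which is exactly
#' the Phred error model the caller assumes.
#'
#' @param reference A [mito_reference()].
#' @param truth A `mito_truth` from [spike_variants()] (or NULL for none).
#' @param coverage Nominal mean coverage (x).
#' @param read_len Read length (default 150).
#' @param base_qual Constant Phred base quality (default 30).
#' @param error_rate Per-base error probability; default
#'   `phred_to_error(base_qual)`. Set 0 for error-free reads.
#' @param seed Integer seed.
#' @return Read data.frame as from [read_alignments()].
#' @export
simulate_reads <- function(reference, truth = NULL, coverage = 100,
                           read_len = 150L, base_qual = 30L,
                           error_rate = NULL, seed = 1L) {
  stopifnot(coverage > 0)
  L <- reference$length
  if (read_len > L) stop("read length exceeds reference length")
  if (is.null(error_rate)) error_rate <- phred_to_error(base_qual)
  if (is.null(truth)) {
    truth <- data.frame(pos = integer(0), ref = character(0),
                        alt = character(0), type = character(0),
                        target_vaf = numeric(0), stringsAsFactors = FALSE)
  }
  n_reads <- max(1L, as.integer(round(coverage * L / read_len)))

  with_seed(seed, {
    starts <- sample.int(L - read_len + 1L, n_reads, replace = TRUE)
    flags <- sample(c(0L, 16L), n_reads, replace = TRUE)
    seqs <- substring(reference$sequence, starts, starts + read_len - 1L)

    ## carrier assignment: read x variant, only for full overlap
    carried <- vector("list", nrow(truth))
    for (v in seq_len(nrow(truth))) {
      span_end <- truth$pos[v] +
        if (truth$type[v] == "INS") 1L else nchar(truth$ref[v]) - 1L
      over <- which(starts <= truth$pos[v] & starts + read_len - 1L >= span_end)
      if (!length(over)) { carried[[v]] <- integer(0); next }
      carried[[v]] <- over[stats::runif(length(over)) < truth$target_vaf[v]]
    }

    ## reads carrying at least one indel need per-read reconstruction
    indel_vs <- which(truth$type %in% c("INS", "DEL"))
    indel_reads <- sort(unique(unlist(carried[indel_vs])))

    ## SNVs on plain reads: vectorized substring replacement
    for (v in which(truth$type == "SNV")) {
      idx <- setdiff(carried[[v]], indel_reads)
      if (!length(idx)) next
      off <- truth$pos[v] - starts[idx] + 1L
      ss <- seqs[idx]
      substr(ss, off, off) <- rep(truth$alt[v], length(idx))
      seqs[idx] <- ss
    }

    cigars <- rep(paste0(read_len, "M"), n_reads)
    for (r in indel_reads) {
      edits <- which(vapply(carried, function(x) r %in% x, logical(1)))
      built <- construct_read(starts[r], read_len, truth[edits, , drop = FALSE],
                              reference)
      seqs[r] <- built$seq
      cigars[r] <- built$cigar
    }

    ## sequencing errors
    lens <- nchar(seqs)
    if (error_rate > 0) {
      total <- sum(lens)
      n_err <- stats::rbinom(1L, total, error_rate)
      if (n_err > 0L) {
        at <- sort(sample.int(total, n_err))
        ends <- cumsum(lens)
        rd <- findInterval(at - 1L, ends) + 1L
        off <- at - c(0L, ends)[rd]
        old <- match(substr(seqs[rd], off, off), BASES)
        new_base <- BASES[(old - 1L + sample.int(3L, n_err, replace = TRUE)) %% 4L + 1L]
        dup <- duplicated(rd) | duplicated(rd, fromLast = TRUE)
        if (any(!dup)) {
          i <- which(!dup)
          ss <- seqs[rd[i]]
          substr(ss, off[i], off[i]) <- new_base[i]
          seqs[rd[i]] <- ss
        }
        for (k in which(dup)) {
          substr(seqs[rd[k]], off[k], off[k]) <- new_base[k]
        }
      }
    }

    reads <- data.frame(
      qname = sprintf("r%07d", seq_len(n_reads)),
      flag = flags,
      rname = reference$name,
      pos = starts,
      mapq = 60L,
      cigar = cigars,
      seq = seqs,
      qual = strrep(intToUtf8(base_qual + 33L), lens),
      stringsAsFactors = FALSE
    )
    attr(reads, "contigs") <- reference$name
    attr(reads, "malformed") <- 0L
    reads
  })
}

## Build one read that carries the given (normalized, position-sorted)
## variant edits: returns list(seq, cigar). The read keeps query length
## `read_len` unless it would run off the reference end.
construct_read <- function(start, read_len, edits, reference) {
  edits <- edits[order(edits$pos), , drop = FALSE]
  snvs <- edits[edits$type == "SNV", , drop = FALSE]
  indels <- edits[edits$type != "SNV", , drop = FALSE]
  L <- reference$length

  take_match <- function(a, b) {
    seg <- substring(reference$sequence, a, b)
    if (nrow(snvs)) {
      hit <- which(snvs$pos >= a & snvs$pos <= b)
      for (h in hit) {
        substr(seg, snvs$pos[h] - a + 1L, snvs$pos[h] - a + 1L) <- snvs$alt[h]
      }
    }
    seg
  }

  parts <- character(0)
  ops <- character(0)
  lens <- integer(0)
  push <- function(op, n, s = NULL) {
    if (n <= 0L) return(invisible())
    if (length(ops) && ops[length(ops)] == op) {
      lens[length(lens)] <<- lens[length(lens)] + n
    } else {
      ops[length(ops) + 1L] <<- op
      lens[length(lens) + 1L] <<- n
    }
    if (!is.null(s)) parts[length(parts) + 1L] <<- s
  }

  cursor <- start
  q_left <- read_len
  for (v in seq_len(nrow(indels))) {
    if (q_left <= 0L) break
    anchor <- indels$pos[v]
    if (anchor < cursor) next
    span <- min(anchor - cursor + 1L, q_left)
    push("M", span, take_match(cursor, cursor + span - 1L))
    cursor <- cursor + span
    q_left <- q_left - span
    if (q_left <= 0L) break
    if (indels$type[v] == "INS") {
      ins <- substr(indels$alt[v], 2L, nchar(indels$alt[v]))
      take <- min(nchar(ins), q_left)
      push("I", take, substr(ins, 1L, take))
      q_left <- q_left - take
    } else {
      del_len <- nchar(indels$ref[v]) - 1L
      push("D", del_len)
      cursor <- cursor + del_len
    }
  }
  if (q_left > 0L) {
    tail_end <- min(cursor + q_left - 1L, L)
    if (tail_end >= cursor) {
      push("M", tail_end - cursor + 1L, take_match(cursor, tail_end))
    }
  }
  ## a trailing D carries no evidence; drop it
  if (length(ops) && ops[length(ops)] == "D") {
    ops <- ops[-length(ops)]
    lens <- lens[-length(lens)]
  }
  list(
    seq = paste(parts, collapse = ""),
    cigar = paste0(lens, ops, collapse = "")
  )
}

#' Score calls against a truth set
#'
#' Matches on exact (pos, ref, alt) after normalization, overall and split
#' by variant class (SNV vs INS+DEL).
#'
#' @param calls A `mito_calls` data.frame (normalized).
#' @param truth A `mito_truth` data.frame.
#' @return A `mito_eval` list with elements `all`, `snv`, `indel`, each
#'   holding tp, fp, fn and all_sites (= tp + fp).
#' @export
evaluate_calls <- function(calls, truth) {
  key <- function(d) paste(d$pos, d$ref, d$alt)
  score <- function(c_keys, t_keys) {
    tp <- sum(t_keys %in% c_keys)
    fp <- length(c_keys) - sum(c_keys %in% t_keys)
    list(tp = tp, fp = fp, fn = length(t_keys) - tp,
         all_sites = length(unique(c_keys)))
  }
  ck <- unique(key(calls))
  tk <- key(truth)
  is_indel_call <- calls$type %in% c("INS", "DEL")
  is_indel_truth <- truth$type %in% c("INS", "DEL")
  structure(list(
    all = score(ck, tk),
    snv = score(unique(key(calls[!is_indel_call, , drop = FALSE])),
                key(truth[!is_indel_truth, , drop = FALSE])),
    indel = score(unique(key(calls[is_indel_call, , drop = FALSE])),
                  key(truth[is_indel_truth, , drop = FALSE]))
  ), class = "mito_eval")
}

#' @export
print.mito_eval <- function(x, ...) {
  row <- function(nm, s) sprintf("  %-6s all_sites=%d tp=%d fp=%d fn=%d",
                                 nm, s$all_sites, s$tp, s$fp, s$fn)
  cat("<mito_eval>\n", row("all", x$all), "\n", row("SNV", x$snv), "\n",
      row("indel", x$indel), "\n", sep = "")
  invisible(x)
}
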