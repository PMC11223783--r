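## Pileup engine: converts quality-filtered reads into per-position,
## per-strand base counts plus indel observations. Base observations are
## stored in a compressed-but-lossless layout: because the genotype
## likelihood depends on an observation only through (base, quality), and
## the strand gate only through (base, strand), the full observation list
## collapses to two count arrays without losing information:
##   counts    [pos, base, strand]   strand 1 = forward, 2 = reverse
##   bq_counts [pos, base, qual]     qual axis = sorted unique Phred values
##
## Reads whose CIGAR is a single M run take a fully vectorized path
## (tabulate over an integer key); reads with indels/clips are walked
## per-CIGAR-op. This is what keeps 2000x whole-molecule samples tractable.

BASES <- c("A", "C", "G", "T")

#' Build a pileup from aligned reads
#'
#' Walks each read's CIGAR: M/=/X operations contribute a base observation
#' at their reference position when the base quality and the read's mapping
#' quality pass the floors; I operations record an insertion anchored at the
#' preceding reference position; D operations record a deletion anchored at
#' the base before the deleted span. Soft clips and N bases contribute
#' nothing. Reads extending past the reference end are truncated and
#' tallied.
#'
#' @param reads Read data.frame from [read_alignments()] / [simulate_reads()].
#' @param reference A [mito_reference()].
#' @param min_baseq Minimum Phred base quality for a base observation.
#' @param min_mapq Minimum read mapping quality.
#' @return An object of class `mito_pileup`: list with `counts`
#'   (length x 4 x 2 integer array), `bq_counts` (length x 4 x n_qual, with
#'   `dimnames` carrying the Phred values), `depth`, `mean_baseq`, `indels`
#'   (data.frame pos/kind/seq/fwd/rev/depth_anchor), `n_clipped_at_end`,
#'   and the filter settings used.
#' @export
build_pileup <- function(reads, reference, min_baseq = 20L, min_mapq = 20L) {
  stopifnot(inherits(reference, "mito_reference"))
  L <- reference$length

  reads <- reads[reads$mapq >= min_mapq, , drop = FALSE]
  simple <- grepl("^[0-9]+M$", reads$cigar)
  n_clipped <- 0L
  parts <- list()

  ## fast path: pure-match reads, expanded with vectorized index arithmetic
  if (any(simple)) {
    r_pos <- reads$pos[simple]
    r_seq <- reads$seq[simple]
    r_qual <- reads$qual[simple]
    r_flag <- reads$flag[simple]
    lens <- nchar(r_seq)
    over <- r_pos + lens - 1L > L
    n_clipped <- n_clipped + sum(over)
    keep_len <- if (any(over)) pmin(lens, L - r_pos + 1L) else lens
    ok <- keep_len > 0L
    if (!all(ok)) {
      r_pos <- r_pos[ok]; r_seq <- r_seq[ok]; r_qual <- r_qual[ok]
      r_flag <- r_flag[ok]; lens <- lens[ok]; keep_len <- keep_len[ok]
    }
    if (length(r_pos)) {
      pos_v <- sequence(keep_len, from = r_pos)
      base_chr <- utf8ToInt(paste(r_seq, collapse = ""))
      qual_v <- utf8ToInt(paste(r_qual, collapse = "")) - 33L
      if (!all(keep_len == lens)) {
        ## some reads clamped at the reference end: index the kept prefix
        idx <- rep.int(cumsum(c(0L, lens))[seq_along(lens)], keep_len) +
          sequence(keep_len, from = 1L)
        base_chr <- base_chr[idx]
        qual_v <- qual_v[idx]
      }
      parts[[length(parts) + 1L]] <- list(
        pos = pos_v, base = base_code(base_chr), qual = qual_v,
        strand = rep.int(as.integer(bitwAnd(r_flag, FLAG_REVERSE) != 0L), keep_len)
      )
    }
  }

  indel_rows <- list()
  if (any(!simple)) {
    rc <- reads[!simple, , drop = FALSE]
    acc_pos <- vector("list", nrow(rc))
    acc_base <- vector("list", nrow(rc))
    acc_qual <- vector("list", nrow(rc))
    acc_strand <- vector("list", nrow(rc))
    for (i in seq_len(nrow(rc))) {
      walk <- walk_cigar(rc$cigar[i], rc$pos[i], rc$seq[i], rc$qual[i], L)
      n_clipped <- n_clipped + walk$clipped
      acc_pos[[i]] <- walk$pos
      acc_base[[i]] <- walk$base
      acc_qual[[i]] <- walk$qual
      rev_i <- as.integer(bitwAnd(rc$flag[i], FLAG_REVERSE) != 0L)
      acc_strand[[i]] <- rep.int(rev_i, length(walk$pos))
      if (nrow(walk$indels)) {
        walk$indels$strand <- rev_i
        indel_rows[[length(indel_rows) + 1L]] <- walk$indels
      }
    }
    parts[[length(parts) + 1L]] <- list(
      pos = unlist(acc_pos, use.names = FALSE),
      base = unlist(acc_base, use.names = FALSE),
      qual = unlist(acc_qual, use.names = FALSE),
      strand = unlist(acc_strand, use.names = FALSE)
    )
  }

  ## drop observations failing the quality floor or with non-ACGT bases;
  ## the cheap min() pre-checks make the common clean case copy-free
  quals <- integer(0)
  for (k in seq_along(parts)) {
    p <- parts[[k]]
    if (!length(p$pos)) next
    if (min(p$base) < 1L || min(p$qual) < min_baseq) {
      keep <- p$base > 0L & p$qual >= min_baseq
      parts[[k]] <- p <- lapply(p, `[`, keep)
    }
    if (length(p$qual)) {
      qmin <- min(p$qual)
      qmax <- max(p$qual)
      quals <- union(quals, if (qmin == qmax) qmin else unique(p$qual))
    }
  }
  quals <- sort(quals)
  nq <- max(1L, length(quals))

  ## tabulate each part into shared bins; counts by (pos, base, strand)
  ## and by (pos, base, qual level)
  cnt_bins <- numeric(8L * L)
  bq_bins <- if (length(quals) > 1L) numeric(4L * L * length(quals)) else NULL
  for (p in parts) {
    if (!length(p$pos)) next
    base_key <- p$pos + L * (p$base - 1L)
    cnt_bins <- cnt_bins + tabulate(base_key + 4L * L * p$strand, nbins = 8L * L)
    if (!is.null(bq_bins)) {
      bq_bins <- bq_bins +
        tabulate(base_key + 4L * L * (match(p$qual, quals) - 1L),
                 nbins = 4L * L * length(quals))
    }
  }
  counts <- array(as.integer(cnt_bins), dim = c(L, 4L, 2L),
                  dimnames = list(NULL, BASES, c("fwd", "rev")))
  if (is.null(bq_bins)) {
    ## single quality level: the by-quality table is the strand-summed table
    bq_counts <- array(
      counts[, , 1L] + counts[, , 2L],
      dim = c(L, 4L, 1L),
      dimnames = list(NULL, BASES, as.character(if (length(quals)) quals else 0L))
    )
  } else {
    bq_counts <- array(as.integer(bq_bins), dim = c(L, 4L, nq),
                       dimnames = list(NULL, BASES, as.character(quals)))
  }

  depth <- as.integer(rowSums(counts, dims = 1L))
  qual_levels <- if (length(quals)) quals else 0L
  qual_sum <- numeric(L)
  for (k in seq_along(qual_levels)) {
    qual_sum <- qual_sum + rowSums(bq_counts[, , k, drop = FALSE]) * qual_levels[k]
  }
  mean_baseq <- ifelse(depth > 0L, qual_sum / depth, NA_real_)

  indels <- aggregate_indels(indel_rows, depth)
  del <- indels$kind == "DEL"
  if (any(del)) {
    indels$seq[del] <- substring(
      reference$sequence, indels$pos[del] + 1L, indels$pos[del] + indels$del_len[del]
    )
  }

  structure(
    list(
      reference = reference, counts = counts, bq_counts = bq_counts,
      quals = qual_levels, depth = depth, mean_baseq = mean_baseq,
      indels = indels, n_clipped_at_end = n_clipped,
      min_baseq = min_baseq, min_mapq = min_mapq
    ),
    class = "mito_pileup"
  )
}

## Map ASCII base codes to 1..4 (A,C,G,T); 0 for anything else (N etc).
base_code <- function(ascii) {
  map <- integer(128L)
  map[utf8ToInt("A")] <- 1L
  map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L
  map[utf8ToInt("T")] <- 4L
  map[utf8ToInt("a")] <- 1L
  map[utf8ToInt("c")] <- 2L
  map[utf8ToInt("g")] <- 3L
  map[utf8ToInt("t")] <- 4L
  map[ascii]
}

## Walk one read's CIGAR; returns base observations and indel observations.
walk_cigar <- function(cigar, pos, seq, qual, ref_len) {
  ops <- cigar_ops(cigar)
  seq_i <- utf8ToInt(seq)
  qual_i <- utf8ToInt(qual) - 33L
  rpos <- pos
  qpos <- 1L
  out_pos <- integer(0)
  out_base <- integer(0)
  out_qual <- integer(0)
  ind <- list()
  clipped <- 0L
  for (k in seq_along(ops$op)) {
    n <- ops$len[k]
    op <- ops$op[k]
    if (op %in% c("M", "=", "X")) {
      take <- n
      if (rpos + n - 1L > ref_len) {
        take <- max(0L, ref_len - rpos + 1L)
        clipped <- 1L
      }
      if (take > 0L) {
        out_pos <- c(out_pos, rpos:(rpos + take - 1L))
        out_base <- c(out_base, base_code(seq_i[qpos:(qpos + take - 1L)]))
        out_qual <- c(out_qual, qual_i[qpos:(qpos + take - 1L)])
      }
      rpos <- rpos + n
      qpos <- qpos + n
    } else if (op == "I") {
      anchor <- rpos - 1L
      if (anchor >= 1L && anchor <= ref_len) {
        ind[[length(ind) + 1L]] <- data.frame(
          pos = anchor, kind = "INS",
          seq = intToUtf8(seq_i[qpos:(qpos + n - 1L)]),
          stringsAsFactors = FALSE
        )
      }
      qpos <- qpos + n
    } else if (op == "D") {
      anchor <- rpos - 1L
      if (anchor >= 1L && rpos + n - 1L <= ref_len) {
        ind[[length(ind) + 1L]] <- data.frame(
          pos = anchor, kind = "DEL", seq = "", del_len = n,
          stringsAsFactors = FALSE
        )
      }
      rpos <- rpos + n
    } else if (op %in% c("S", "H", "P")) {
      if (op == "S") qpos <- qpos + n
    } else if (op == "N") {
      rpos <- rpos + n
    }
  }
  ind_df <- if (length(ind)) rbind2_fill(ind) else
    data.frame(pos = integer(0), kind = character(0), seq = character(0),
               del_len = integer(0), stringsAsFactors = FALSE)
  list(pos = out_pos, base = out_base, qual = out_qual,
       indels = ind_df, clipped = clipped)
}

## rbind a list of small data.frames, padding the optional del_len column.
rbind2_fill <- function(lst) {
  lst <- lapply(lst, function(d) {
    if (is.null(d$del_len)) d$del_len <- NA_integer_
    d
  })
  do.call(rbind, lst)
}

## Aggregate per-read indel observations by (pos, kind, seq) with per-strand
## counts; deletion seq is resolved against the reference later (caller has
## it via the pileup object).
aggregate_indels <- function(indel_rows, depth) {
  if (!length(indel_rows)) {
    return(data.frame(
      pos = integer(0), kind = character(0), seq = character(0),
      del_len = integer(0), fwd = integer(0), rev = integer(0),
      depth_anchor = integer(0), stringsAsFactors = FALSE
    ))
  }
  all <- do.call(rbind, lapply(indel_rows, function(d) {
    if (is.null(d$del_len)) d$del_len <- NA_integer_
    d
  }))
  key <- paste(all$pos, all$kind, all$seq, all$del_len, sep = "\r")
  agg <- data.frame(
    key = names(table(key)), stringsAsFactors = FALSE
  )
  fwd <- tapply(all$strand == 0L, key, sum)
  rev <- tapply(all$strand == 1L, key, sum)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  out <- data.frame(
    pos = as.integer(vapply(parts, `[[`, character(1), 1L)),
    kind = vapply(parts, `[[`, character(1), 2L),
    seq = vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else "", character(1)),
    del_len = suppressWarnings(as.integer(vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else "NA", character(1)))),
    fwd = as.integer(fwd[agg$key]),
    rev = as.integer(rev[agg$key]),
    stringsAsFactors = FALSE
  )
  out$depth_anchor <- depth[out$pos]
  out <- out[order(out$pos, out$kind, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.mito_pileup <- function(x, ...) {
  cat(sprintf(
    "<mito_pileup> %s: %d positions, mean depth %.1fx, %d indel observation classes\n",
    x$reference$name, length(x$depth), mean(x$depth), nrow(x$indels)
  ))
  invisible(x)
}

#' Per-position coverage table
#'
#' @param pileup A `mito_pileup`.
#' @return data.frame with pos, depth, mean_baseq.
#' @export
coverage_table <- function(pileup) {
  stopifnot(inherits(pileup, "mito_pileup"))
  data.frame(
    pos = seq_along(pileup$depth),
    depth = pileup$depth,
    mean_baseq = pileup$mean_baseq
  )
}
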