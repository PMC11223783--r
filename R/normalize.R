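## VCF normalization (multiallelic splitting + left alignment with
## parsimonious alleles) and the fusion merge that combines the SNV
## caller's output with an indel call set, favoring the indel when both
## callers report at the same position.

#' Split a multiallelic VCF record into biallelic records
#'
#' One record per alternate allele, preserving allele order; the AF of a
#' comma-separated AF field follows its allele, site-level fields are
#' copied.
#'
#' @param record One-row VCF record data.frame (as from [read_vcf()]);
#'   `alt` may be a comma-separated allele list and `af` may be a
#'   comma-separated string or single number.
#' @return data.frame with one row per alternate allele.
#' @export
split_multiallelic <- function(record) {
  stopifnot(nrow(record) == 1L)
  alts <- strsplit(record$alt, ",", fixed = TRUE)[[1]]
  if (length(alts) <= 1L) {
    return(record)
  }
  afs <- if (is.character(record$af)) {
    suppressWarnings(as.numeric(strsplit(record$af, ",", fixed = TRUE)[[1]]))
  } else {
    rep(record$af, length(alts))
  }
  if (length(afs) != length(alts)) afs <- rep(afs[1], length(alts))
  out <- record[rep(1L, length(alts)), , drop = FALSE]
  out$alt <- alts
  out$af <- afs
  rownames(out) <- NULL
  out
}

## Variant type from a biallelic ref/alt pair.
allele_type <- function(ref, alt) {
  ifelse(nchar(ref) == nchar(alt), "SNV",
         ifelse(nchar(alt) > nchar(ref), "INS", "DEL"))
}

#' Left-align and trim one biallelic variant
#'
#' Produces the canonical parsimonious representation: repeatedly drop a
#' shared trailing base (re-extending to the left from the reference when
#' an allele would empty), then drop shared leading bases while both
#' alleles keep at least one base. SNVs are already canonical and pass
#' through unchanged.
#'
#' @param pos 1-based position.
#' @param ref,alt Allele strings (non-empty, matching the reference
#'   context).
#' @param reference A [mito_reference()].
#' @return List with `pos`, `ref`, `alt`, `type`.
#' @export
normalize_variant <- function(pos, ref, alt, reference) {
  stopifnot(nzchar(ref), nzchar(alt))
  if (nchar(ref) == 1L && nchar(alt) == 1L) {
    return(list(pos = pos, ref = ref, alt = alt, type = "SNV"))
  }
  repeat {
    rl <- nchar(ref); al <- nchar(alt)
    if (max(rl, al) >= 2L &&
        substr(ref, rl, rl) == substr(alt, al, al)) {
      ref <- substr(ref, 1L, rl - 1L)
      alt <- substr(alt, 1L, al - 1L)
      if (!nzchar(ref) || !nzchar(alt)) {
        if (pos <= 1L) stop("cannot left-extend past contig start")
        pos <- pos - 1L
        b <- ref_bases(reference, pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    } else {
      break
    }
  }
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt, type = allele_type(ref, alt))
}

#' Normalize every record of a call set
#'
#' @param calls A `mito_calls` data.frame (biallelic records).
#' @param reference A [mito_reference()].
#' @return The call set with pos/ref/alt/type normalized, re-sorted by
#'   position.
#' @export
normalize_calls <- function(calls, reference) {
  if (!nrow(calls)) return(calls)
  for (i in seq_len(nrow(calls))) {
    n <- normalize_variant(calls$pos[i], calls$ref[i], calls$alt[i], reference)
    calls$pos[i] <- n$pos
    calls$ref[i] <- n$ref
    calls$alt[i] <- n$alt
    calls$type[i] <- n$type
  }
  calls <- calls[order(calls$pos, calls$type, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

## TRUE when a record still carries a shared leading/trailing base pattern
## the normalizer would remove (used to reject unnormalized merge input).
is_normalized <- function(pos, ref, alt, reference) {
  n <- normalize_variant(pos, ref, alt, reference)
  n$pos == pos && n$ref == ref && n$alt == alt
}

#' Merge SNV and indel call sets (fusion mode)
#'
#' Takes every INS/DEL record from the indel caller and every SNV record
#' from the Bayesian caller whose position does not collide with a retained
#' indel; SNV-type records in the indel set are discarded (SNVs come only
#' from the Bayesian caller). The collision key is the position alone.
#'
#' @param snv_calls,indel_calls `mito_calls` data.frames, normalized and
#'   biallelic.
#' @param reference A [mito_reference()] used to verify normalization.
#' @return Merged `mito_calls`, position-sorted and unique on
#'   (pos, ref, alt).
#' @export
merge_fusion <- function(snv_calls, indel_calls, reference) {
  check_norm <- function(calls, label) {
    if (!nrow(calls)) return(invisible())
    for (i in seq_len(nrow(calls))) {
      if (!is_normalized(calls$pos[i], calls$ref[i], calls$alt[i], reference)) {
        stop(sprintf("unnormalized %s record at pos %d (%s>%s); run normalize_calls() first",
                     label, calls$pos[i], calls$ref[i], calls$alt[i]))
      }
    }
  }
  check_norm(snv_calls, "SNV")
  check_norm(indel_calls, "indel")

  ind <- indel_calls[indel_calls$type %in% c("INS", "DEL"), , drop = FALSE]
  snv <- snv_calls[snv_calls$type == "SNV", , drop = FALSE]
  snv <- snv[!(snv$pos %in% ind$pos), , drop = FALSE]
  out <- rbind(as.data.frame(snv), as.data.frame(ind))
  out <- out[!duplicated(out[, c("pos", "ref", "alt")]), , drop = FALSE]
  out <- out[order(out$pos, out$type, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mito_calls", "data.frame")
  out
}
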