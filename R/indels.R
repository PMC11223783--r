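#' Naive pileup indel caller
#'
#' Groups the pileup's indel observations by (position, kind, sequence) and
#' emits a call whenever the group's frequency against the base depth at
#' the anchor position clears the detection floor with support on both
#' strands. This is a deliberately simple frequency caller: it has no
#' haplotype assembly and no homopolymer-aware error model, so it is
#' expected to trail a full somatic indel caller on hard contexts; it
#' exists so the fusion merge has an indel arm.
#'
#' Calls use the VCF anchor convention: a deletion of `S` after position p
#' becomes `pos = p, ref = base(p) + S, alt = base(p)`; an insertion of `S`
#' after p becomes `pos = p, ref = base(p), alt = base(p) + S`. Emitted
#' records are left-aligned already whenever the observations were (the
#' normalizer is a fixpoint on them after left alignment).
#'
#' @param pileup A `mito_pileup`.
#' @param min_vaf Minimum indel allele frequency (default 0.02).
#' @param min_count_per_strand Minimum supporting reads per strand (default 2).
#' @param min_depth Minimum anchor depth (default 10).
#' @return A `mito_calls` data.frame (possibly empty).
#' @export
call_indels <- function(pileup, min_vaf = 0.02, min_count_per_strand = 2L,
                        min_depth = 10L) {
  stopifnot(inherits(pileup, "mito_pileup"))
  obs <- pileup$indels
  ref <- pileup$reference
  if (!nrow(obs)) {
    out <- empty_calls()
    class(out) <- c("mito_calls", "data.frame")
    return(out)
  }
  n <- obs$fwd + obs$rev
  vaf <- ifelse(obs$depth_anchor > 0L, n / obs$depth_anchor, NA_real_)
  keep <- !is.na(vaf) & vaf >= min_vaf &
    obs$fwd >= min_count_per_strand & obs$rev >= min_count_per_strand &
    obs$depth_anchor >= min_depth
  obs <- obs[keep, , drop = FALSE]
  if (!nrow(obs)) {
    out <- empty_calls()
    class(out) <- c("mito_calls", "data.frame")
    return(out)
  }
  anchor <- ref_bases(ref, obs$pos)
  ins <- obs$kind == "INS"
  out <- data.frame(
    pos = obs$pos,
    ref = ifelse(ins, anchor, paste0(anchor, obs$seq)),
    alt = ifelse(ins, paste0(anchor, obs$seq), anchor),
    type = ifelse(ins, "INS", "DEL"),
    vaf = (obs$fwd + obs$rev) / obs$depth_anchor,
    depth = obs$depth_anchor,
    n_alt = obs$fwd + obs$rev,
    alt_fwd = obs$fwd,
    alt_rev = obs$rev,
    mean_baseq = pileup$mean_baseq[obs$pos],
    gt = "0/1",
    filter = "PASS",
    src = "indel-standin",
    stringsAsFactors = FALSE
  )
  out <- out[order(out$pos, out$type, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mito_calls", "data.frame")
  out
}
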