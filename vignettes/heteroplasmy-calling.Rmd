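---
title: "Methods: Bayesian heteroplasmy calling, fusion merging and coverage-aware filtering"
author: "mitovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian heteroplasmy calling, fusion merging and coverage-aware filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitovar)
```

# Scope and model

`mitovar` analyses reads aligned to a single mitochondrial contig. The
mitochondrial genome is polyploid within a cell, so the object of inference
at each position is not a diploid genotype but the allele fraction of a
possible second allele: *homoplasmy* (one allele) versus *heteroplasmy*
(two alleles at fractions f and 1 − f). The package covers the full desk
workflow: input QC, pileup construction, Bayesian SNV calling, a simple
pileup indel caller, normalization and fusion merging of the two call sets,
a binomial model of what allele fraction the local coverage can support,
deterministic subsampling, and a read simulator used for benchmarking.

## Genotype posterior

At a position with observations (b_j, q_j), each base contributes through
the standard Phred error probability e_j = 10^(−q_j/10), clamped to
[10^−6, 0.75] — the lower clamp stops a single miscalibrated Q60+ base from
dominating a log-likelihood, the upper keeps 1 − e informative at q = 0.
The hypothesis space per column is:

* HOM(X), X ∈ {A, C, G, T}: P(b | HOM X) = 1 − e if b = X, else e/3.
* HET(M, m) for every unordered base pair with both bases observed:
  P(b | HET) = (1 − f) P(b | HOM M) + f P(b | HOM m), with the minor
  fraction f fixed at the empirical fraction n_m / (n_M + n_m) rather than
  integrated over — an empirical-Bayes shortcut that keeps the whole
  genome's scoring a handful of matrix operations.

The prior gives mass 1 − θ_het to the homoplasmic hypotheses, split in
proportion to population allele frequencies (uniform 0.25 by default; a
per-position TSV can be supplied, with a 10^−4 floor and renormalization so
no base is ever impossible a priori), and θ_het (default 0.01) split
equally over the candidate heteroplasmic pairs at the column. Posteriors
are computed in log space and normalized. These modelling choices — the
mixture form of the heteroplasmic likelihood, the value of θ_het, and the
per-strand support rule below — are this package's own design decisions;
the general ingredients (population-frequency prior, base-quality
likelihood, maximum-posterior genotype) are the field's standard recipe.

A call is emitted when the maximum-posterior hypothesis disagrees with the
reference: a non-reference homoplasmic winner becomes a VAF 1.0 call, and a
heteroplasmic winner becomes a heteroplasmy call at the non-reference
allele's level L, accepted only if L ≥ `min_vaf` (default 0.02) and the
minor allele has at least `min_minor_per_strand` (default 2) observations
on *each* strand; otherwise the column falls back to the homoplasmic
interpretation of the major allele. Posterior ties are broken toward
reference-containing hypotheses, then alphabetically, implemented as a
deterministic infinitesimal bias so the vectorized and per-column code
paths agree. The test suite cross-checks the vectorized caller against the
readable per-column implementation (`posterior_genotypes()`) — one model,
two routes.

## Indel calling and the fusion merge

The indel arm is a deliberately naive frequency caller on the pileup's
indel observations (insertions anchored at the base before the event;
deletions likewise, with the deleted span taken from the reference). A
group is called when count/depth-at-anchor ≥ `min_vaf` with at least 2
supporting reads per strand and anchor depth ≥ `min_depth`. It has no
haplotype assembly and no homopolymer error model, so on hard real-data
contexts it will trail a full somatic indel caller; it exists to give the
fusion merge an indel input, and any external indel VCF can be substituted
through the `merge` interface.

Before merging, records are normalized: multiallelic records are split one
record per alternate allele (per-allele AF following its allele), and each
biallelic record is reduced to the canonical left-aligned parsimonious form
by the standard trim/extend loop (drop shared trailing bases, re-extending
to the left from the reference when an allele would empty; then drop shared
leading bases while both alleles keep ≥ 2 bases). The normalizer is
idempotent and is verified against an enumeration oracle that generates all
equivalent representations of an event and selects the most parsimonious,
left-most one. The merge itself takes all INS/DEL records from the indel
set and all SNV records from the Bayesian set whose position does not
collide with a retained indel; SNV-type records in the indel set are
discarded. The collision key is the *position alone* — the coarser of the
two defensible choices (the alternative being overlap of reference spans);
it is simpler, deterministic, and errs toward trusting the indel caller at
a contested site.

## Minimal trusted VAF

Whether an observed allele fraction means anything depends on depth and
base quality. With per-base error probability p (from the mean base
quality — the alt-supporting observations' mean where available, else the
column mean) and depth N, the number of alt-looking reads from error alone
is X ~ Binomial(N, p). The minimal trusted count k\* is the smallest k with
P(X ≥ k) < α (default α = 0.05, strict inequality); the minimal trusted
VAF is k\*/N, and k\* = N + 1 encodes "not achievable at this depth". The
tail is computed with the stable upper-tail `pbinom()`; the contract — and
the test — is exact agreement with brute-force summation of the binomial
mass for N ≤ 10^4. Calls with fewer than k\* alt reads are *flagged*, never
removed, and the mean of k\*/N over covered positions is reported per
sample as its detection floor. At 2000× and Q30 the floor is ≈ 0.3%, which
is why 2% is a comfortable default detection level at that depth.

## Subsampling

Very deep samples are subsampled to a target mean coverage (default 2000×)
by keeping each read with probability min(1, target/mean). The keep
decision is a pure function of (seed, read name) — a 32-bit FNV-1a hash of
the name mixed with the seed and mapped to [0, 1) — so re-runs are
byte-identical, the kept set is invariant under input reordering, and mates
sharing a name travel together, all with a single pass. The default seed is
a fixed documented constant (`MITOVAR_SUBSAMPLE_SEED`), overridable.

# The simulator and what passing tests mean

The simulator generates a uniform-composition random reference (default
16,569 bp, the size of the standard human mtDNA reference), spikes a truth
set (SNVs with a random non-reference base; 1–5 bp insertions/deletions;
positions ≥ 10 bp apart; every record emitted already normalized), and
places fixed-length single-end reads uniformly. Each read independently
carries every truth variant it fully overlaps with probability equal to the
variant's target VAF, indels are realized in the read sequence and CIGAR
(reads are "pre-aligned" by construction), and sequencing errors are
substituted per base at the Phred rate of the constant quality (Q30 →
0.1%), which is exactly the error model the caller assumes.

That last point delimits what the benchmarks show: they demonstrate the
machinery is correct *under its own error model* — VAF recovery, gate
behaviour, normalization, merge semantics, determinism. Real data adds
miscalibrated qualities, strand- and context-dependent errors, homopolymer
indel noise, alignment artifacts around the circular origin, and reads from
nuclear-embedded mitochondrial segments (NUMTs); none of these are
simulated, and the clean false-positive counts here should not be read as a
real-data error rate. Single-end reads are the default because mate
handling is irrelevant to the calling arithmetic and keeps fixtures small;
per-sample haplotype backbones (as a real population benchmark would have)
are not emulated — each sample is reference plus spikes.

## Benchmark conditions

The regenerated gold standard (`run_benchmark()`, also driven by
`scripts/acceptance.R`) uses 30 samples, 35 heteroplasmic SNVs + 8
heteroplasmic indels per sample, target VAFs uniform on [0.02, 0.5],
2000× (and optionally 100×) coverage, 150 bp reads at Q30. One master seed
derives the reference seed and all per-sample truth/read seeds. At these
settings the suite and the acceptance script together take a few minutes on
one CPU; the problem sizes above are the package's chosen benchmark
conditions, stated here so results are interpretable.

Two statistical edges are worth naming. First, a variant spiked *exactly*
at the 2% detection floor sits on the decision boundary: binomial sampling
at 2000× puts roughly half of its realizations below the threshold, so
perfect recall at exactly 2% is not a statistically achievable property of
any thresholded caller, and the tests assert perfect recall only from 5%
upward (VAF accuracy is asserted across the whole range as mean absolute
error < 0.01). Second, the full-versus-subsampled agreement test spikes
VAFs from {5%, 10%, 20%, 50%}: at the floor itself, agreement between two
random thinnings is likewise not guaranteed, and the property under test is
subsampling determinism, not boundary behaviour.

# Numerical and degenerate-input choices

* Posteriors in log space; normalization is tested to |Σ − 1| < 10^−12 on
  every column of noisy samples.
* Depth-0 columns return the prior over homoplasmic hypotheses; columns
  below `min_depth` (default 10) yield no call; a reference `N` yields no
  call.
* Coverage counts only M/=/X bases passing both quality floors (defaults
  Q20/MAPQ20, overridable); deletions add no base depth, and an indel's VAF
  denominator is the base depth at its anchor.
* Reads overhanging the reference end are truncated and tallied; the genome
  is treated as linear, so coverage and calls at the circular junction are
  a documented limitation.
* Overlapping mate pairs are not deduplicated within fragments (single-end
  focus); duplicate-flagged reads are excluded on input by default.
* `min_alt_reads()` returns N + 1 when even k = N is not significant;
  `min_trusted_vaf()` marks such sites (and N = 0) unachievable, and a
  sample with no covered position reports an undefined detection floor.
* QC runs every check and reports *all* violated requirements (not
  fail-fast); the default accepted contig names are
  {chrM, MT, chrMT, NC_012920.1, rCRS} and the default coverage cutoff is
  50× — both exposed as configuration, since no published cutoffs exist to
  inherit.

# Known limitations

The indel caller is a stand-in, not a somatic-caller peer. The prior table
is per-position/per-base only. Circularity, NUMT filtering, contamination
detection, haplogroup assignment and local realignment are out of scope.
BAM input requires Rsamtools; SAM text is the native interchange format.
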