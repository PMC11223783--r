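# mitovar

Desk-scale detection of mitochondrial DNA variants and heteroplasmies from
aligned sequencing reads.

Mitochondria carry hundreds to thousands of genome copies per cell, so a
variant can be present in any fraction of them — a state called
*heteroplasmy*, quantified by the variant allele frequency (VAF). Calling
heteroplasmies down to a few percent requires deep coverage, a caller that
separates low-level signal from sequencing error, and an explicit statement
of what allele fraction the data can support at all. `mitovar` implements
that workflow for a single mitochondrial contig:

- **Bayesian SNV/heteroplasmy calling.** At each position the caller scores
  four homoplasmic hypotheses HOM(X) and candidate heteroplasmic hypotheses
  HET(M, m) with the minor fraction fixed at the empirical fraction
  f = n_m / (n_M + n_m). The likelihood of an observed base b with Phred
  quality q (error probability e = 10^(−q/10)) is

      P(b | HOM X)     = 1 − e        if b = X, else e/3
      P(b | HET M,m,f) = (1 − f) P(b | HOM M) + f P(b | HOM m)

  combined with a prior that spreads (1 − θ_het) over the homoplasmic
  hypotheses in proportion to population allele frequencies (uniform by
  default, per-position table optional) and θ_het over the heteroplasmic
  candidates. The maximum-posterior hypothesis decides the call, gated by a
  VAF floor (2% default) and minor-allele support on both strands.
- **A naive pileup indel caller** (frequency + strand + depth gates) so the
  fusion merge has an indel arm; any external indel VCF can be substituted.
- **Fusion merge with VCF normalization**: indel left-alignment with
  parsimonious alleles, multiallelic splitting, then SNVs from the Bayesian
  caller plus indels from the indel caller, the indel winning positional
  conflicts.
- **Binomial minimal-trusted-VAF model**: at depth N with error probability
  p, the minimal trusted alt-read count k\* is the smallest k with
  P(X ≥ k) < α for X ~ Binomial(N, p); calls with fewer alt reads are
  flagged (`low_vaf_for_coverage`), and the per-sample mean of k\*/N is
  reported as the detection floor.
- **Deterministic subsampling** to a target coverage (2000× default) where
  the keep decision is a seeded hash of the read name — reproducible,
  order-invariant, and mate-pair coherent.
- **QC validation** (contig identity, coverage, quality statistics) with
  JSON/TSV reports, and a **seeded read simulator** that generates
  references, spiked truth sets and error-bearing reads so the whole
  pipeline is testable without any data download.

## Worked example

Simulate one deep sample with 35 heteroplasmic SNVs and 8 heteroplasmic
indels, call it in fusion mode, and score the calls against the truth:

```r
library(mitovar)

ref   <- simulate_reference(16569, seed = 42)
truth <- spike_variants(ref, n_snv = 35, n_indel = 8, seed = 43)
reads <- simulate_reads(ref, truth, coverage = 2000, seed = 44)

res <- run_sample(reads, ref, mode = "fusion", sample_id = "demo",
                  min_vaf_check = TRUE)
print(res$qc)
#> <mito_qc> demo: PASSED
#>   contig chrM; 220920 reads (0 malformed); mean coverage 1999.7x (median 2015x)
#>   mean mapq 60.0; mean baseq 30.0; 100.0% bases >= Q20; mean detectable VAF 0.0029

summary(res$calls)
#> 43 variant call(s); 43 heteroplasmic, 0 flagged
#>
#> DEL INS SNV
#>   6   2  35
#> heteroplasmy VAF range: 0.0277 - 0.5003

evaluate_calls(res$calls, truth)
#> <mito_eval>
#>   all    all_sites=43 tp=43 fp=0 fn=0
#>   SNV    all_sites=35 tp=35 fp=0 fn=0
#>   indel  all_sites=8 tp=8 fp=0 fn=0
```

The QC line says the sample passed validation at ~2000× and that, given its
coverage and base qualities, allele fractions down to ~0.3% are
statistically supportable (so the default 2% floor is comfortably
achievable). The call summary shows all 43 spiked variants recovered with
VAFs from 2.8% to 50%, none flagged by the binomial model, and the
evaluation confirms zero false positives and zero false negatives on this
sample.

A command-line front end wrapping the same functions ships in
`inst/cli/mitovar.R`:

```sh
Rscript inst/cli/mitovar.R simulate --out sim --n-samples 3 --coverage 2000 --seed 1
Rscript inst/cli/mitovar.R call --reference sim/reference.fasta \
    --sam sim/sample001.sam --out calls --mode fusion --min-vaf-check
Rscript inst/cli/mitovar.R evaluate --calls calls/sample001.vcf \
    --truth sim/sample001.truth.vcf
```

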