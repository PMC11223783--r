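Package: mitovar
Title: Mitochondrial Heteroplasmy Detection from Aligned Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for calling single-nucleotide variants and
    heteroplasmies on the mitochondrial genome from aligned sequencing reads.
    Implements a Bayesian per-position genotype model combining a
    population-frequency prior with a base-quality likelihood, a naive pileup
    indel caller, a fusion merge of SNV and indel call sets with VCF
    normalization (left alignment, multiallelic splitting), a binomial model
    of the minimal trusted variant allele frequency given coverage and base
    quality, deterministic seeded read subsampling to a target coverage,
    per-sample quality control, and a seeded read simulator that generates
    references, spiked truth sets and error-bearing reads for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    VariantAnnotation,
    BiocGenerics,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
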