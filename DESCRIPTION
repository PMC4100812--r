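Package: dynexome
Title: Serial-Exome Analysis of Acquired Variants, Microsatellite Dynamics
    and Per-Year Variation Rates
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing exome sequencing samples collected from the
    same individual at different ages. Detects variants acquired or lost
    between time points over the callable intersection of both samples'
    coverage, classifies variants functionally (synonymous, nonsynonymous,
    stop-gain/loss, splicing, frameshift and nonframeshift indels) and
    positionally against gene models, genotypes microsatellite loci from
    spanning reads and compares genotypes across time points (global
    microsatellite index), computes per-base-per-year and per-locus-per-year
    variation rates, ranks recurrently mutated genes across individuals, and
    performs Fisher's exact gene-set enrichment with Bonferroni correction.
    Includes a deterministic synthetic mini-exome study generator with truth
    tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
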