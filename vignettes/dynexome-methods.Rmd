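---
title: "Serial-exome analysis with dynexome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serial-exome analysis with dynexome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynexome)
```

## The procedure

dynexome compares exome samples collected from the *same individual* at
different ages and quantifies how the exome changes over time. The analysis
deliberately avoids the usual framing — differences against a reference
genome — because an individual carries thousands of stable germline
differences from any reference that say nothing about change. What matters
is the set difference between the individual's own time points.

The core procedure, per individual:

1. **Quality filtering.** Calls are kept when read depth ≥ 5 (inclusive)
   and mapping quality > 30 (strict). These asymmetric boundary semantics
   are intentional and pinned by tests.
2. **Callable intersection.** A difference between two samples is only
   declarable where *both* samples had adequate evidence. Positions covered
   by ≥ 5 reads in both coverage tracks form the callable intersection;
   for an indel the entire reference footprint must be callable, for a SNV
   the single base. Variants outside it are reported in a separate
   "unverifiable" audit set, never as acquired or lost — this mirrors the
   read-support verification step that guards against false negatives.
3. **Partition.** Over the callable intersection, variants are partitioned
   by normalized allele-level key (contig, pos, ref, alt) into
   **acquired** (later ∖ earlier), **lost** (earlier ∖ later) and
   **persistent** (both). Comparisons in a ≥ 3-time-point series are always
   anchored at the earliest sample rather than chained consecutively, so a
   variant acquired and subsequently lost appears as acquired in the first
   comparison and is simply absent from later ones — the behaviour needed
   to describe transient, negatively selected variants.
4. **Annotation.** Each differing variant is classified against gene
   models: inside the CDS the affected codon is translated on both alleles
   (strand-aware, standard genetic code) giving synonymous /
   nonsynonymous / stop-gain / stop-loss; intronic positions within 2 bp
   of an intron/exon junction are splicing; coding indels are frameshift
   when their CDS-overlapping length is not divisible by 3; everything
   else receives a positional class (UTR exon/intron, intronic,
   up/downstream within 1 kb, intergenic).
5. **Rates.** The nonsynonymous variation rate is the exact quotient
   `n_nsSNV / (target_bp × years)` in bp⁻¹ year⁻¹. The default denominator
   is the 62.2 Mb exome target; `target_bp = "callable"` uses the measured
   callable width instead, which is the statistically honest denominator
   for small or uneven coverage and is the pipeline default.
6. **Microsatellites.** Repeat loci are genotyped independently of the
   variant calls, from reads whose aligned footprint completely spans the
   tract plus a 2 bp flank. The per-read repeat length is the reference
   tract length adjusted by the net indel length the CIGAR places within
   the tract, divided by the motif length. A genotype needs ≥ 15 spanning
   reads; allele lengths supported by ≥ 30% of spanning reads survive, and
   the top two (ties broken toward the shorter allele) form the diploid
   call. Two samples' genotypes are compared over the loci *called in
   both*; the global microsatellite index is
   `100 × variable / called-in-both`, and the per-locus rate divides the
   variable fraction by elapsed years.
7. **Gene-level statistics.** Differing variants are counted per gene; the
   top-k (default 100, cutoff ties included) lists are intersected across
   individuals to find recurrently mutated genes. Genes carrying
   damaging-flagged variants are tested for term enrichment with a
   one-sided Fisher's exact test; p-values are Bonferroni-multiplied by
   the number of terms actually tested and called significant below 0.05.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `min_depth` | 5 | reads | callability floor, inclusive |
| `min_mq` | 30 | phred-like | strict inequality; removes ambiguous alignments |
| `min_verify_reads` | 5 | reads | read support required in *both* samples |
| `min_spanning` | 15 | reads | repeat loci need more evidence than unique sequence |
| `min_allele_frac` | 0.3 | fraction | diploid allele acceptance; rejects stutter clusters |
| msat flank | 2 | bp | "completely spanning" margin beyond the tract |
| up/downstream window | 1000 | bp | conventional flank for positional annotation |
| `target_bp` | `"callable"` | bp | rate denominator; set 62.2e6 to reproduce fixed-target rates |
| `alpha` | 0.05 | — | significance for Bonferroni-corrected p-values |

The spanning-read allele-acceptance rule is the one genuinely open design
point: the original repeat-genotyping software's thresholds are not
published, so dynexome adopts a transparent fraction threshold and exposes
it as a parameter. At 30%, a diploid call tolerates roughly one stutter
unit class per locus while still rejecting minority noise; loci that are
unstable under alternative settings can be blacklisted from the catalog,
mirroring the practice of removing loci with assembly-version-discordant
genotypes.

## What the synthetic generator emulates

`sim_config()` defaults encode the targeted study design: three
individuals sampled at ages 17/30, 29/45 and 42/51/57; mean coverage 152×;
an acquisition rate of 2×10⁻⁶ bp⁻¹ year⁻¹ (inside the observed
per-individual range of ~1×10⁻⁶–8×10⁻⁶); a microsatellite change rate of
2.5×10⁻⁴ locus⁻¹ year⁻¹; and a small per-year loss probability so that
transient variants occur. Genome geometry is desk-scale — two 100 kb
contigs, 30 four-exon genes, 36 microsatellite loci cycling through all
nine positional classes — chosen so the full pipeline plus the test suite
runs in seconds while still exercising every classification branch
(UTR-only exons and UTR introns exist by construction).

The generator draws acquired-variant counts per time interval from
Poisson(rate × target bp × Δt), places them uniformly over the target
space, draws block-wise negative-binomial coverage (`depth_dispersion = 0`
gives uniform coverage for noise-free tests), and emits spanning reads
whose repeat length is perturbed by ±1 unit with probability
`stutter_prob`. All output files are byte-deterministic given the seed.

It does **not** emulate: realistic base-level sequencing error or quality
profiles; alignment artefacts (reads are emitted pre-aligned with exact
CIGARs, and the stutter model is symmetric where real PCR stutter is
deletion-biased); mutational signatures or clustering of acquired variants
(uniform placement is an assumption, not an inference); multi-allelic
sites arising within one individual; and tumor-like subclonal structure.
Passing truth-recovery tests therefore demonstrates correctness of the
*set logic, classification, genotyping and rate arithmetic*, not
robustness to alignment or chemistry artefacts in real data.

## Numerical conventions and degenerate inputs

* **Coordinates** are 0-based half-open everywhere internally; conversion
  happens only at the VCF boundary (1-based). A single convention
  eliminates a whole class of off-by-one errors.
* **Indel normalization**: alleles are suffix/prefix-trimmed to minimal
  anchored form and left-aligned against the reference before key
  comparison, so the same physical indel written two ways compares equal.
* **Report rounding**: rates are reported at two significant figures by
  truncation toward zero (9.657×10⁻⁷ prints as 9.6×10⁻⁷), percentages at
  one decimal. Truncation is the convention under which every published
  headline rate reproduces exactly from its published inputs; internal
  values are never rounded.
* **Ties** in allele calling break toward higher read count, then the
  shorter allele; ties at the top-k gene cutoff include all tied genes.
* **Degenerate inputs**: identical variant sets give a shared fraction of
  1 (also when both sets are empty); zero variable loci give index 0;
  empty call sets filter to empty; enrichment of a term with no universe
  genes is not tested (and does not inflate the Bonferroni divisor);
  comparisons require strictly increasing ages and distinct sample ids.
* **Genotype-state changes** (het→hom at the same allele) do not count as
  differing by default; `count_genotype_changes = TRUE` enables them as a
  separately reported category. Variant identity is allele-level because
  zygosity transitions in serial bulk samples are dominated by sampling
  noise.
* **Shared fraction** uses the union of both time points' callable
  variants as denominator — the published "~94% present before and after"
  phrasing does not pin one down, and the union is the most conservative
  choice.
* **Enrichment universe** is the set of genes overlapping the target
  intervals, not all genes: only targeted genes could have been observed.
  The Bonferroni divisor is the number of terms actually tested.

## Problem sizes in the test suite

The suite validates against truth on studies of one 60 kb contig, 12
genes and 18 microsatellite loci (about 10 kb of target); Poisson-law and
rate-recovery checks use 20 independent simulations with an expected
~16 acquired variants each; oracle-equivalence checks run 1,000-variant
brute-force scans, 200 random coding SNVs against a
translate-both-haplotypes oracle, and 25 random enrichment tables with
N ≤ 60 against exhaustive hypergeometric tail sums (agreement within
10⁻¹²). Microsatellite concordance is measured at the design coverage of
152× with 2% stutter.

## Known limitations

* Genotyping measures repeat length from the aligned CIGAR, not by
  re-detecting the motif in read sequence; reads misaligned around the
  tract would be measured incorrectly (on simulated data the CIGAR is
  exact).
* The pipeline consumes damaging-variant flags and known-variant catalogs
  as inputs; it performs no damage prediction of its own.
* Stop codons introduced downstream by frameshifts are not counted as
  stop-gain; only codon-local changes are.
* No joint re-genotyping across samples: a variant just below threshold in
  one sample is unverifiable rather than rescued.
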