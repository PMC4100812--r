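# Shared fixtures, built in code. small_config() is a desk-scale noise-off
# study (uniform deep coverage, no stutter, no low-MQ loci) used by the
# deterministic truth-recovery tests; tests needing noise switch it on
# explicitly.

small_config <- function(...) {
  args <- list(
    n_contigs = 1L, contig_length = 60000L, n_genes = 12L,
    exons_per_gene = 4L, n_microsat_loci = 18L,
    baseline_variant_rate = 2e-3, acquired_rate = 2e-4,
    lost_rate = 0.005,
    ages = list(indA = c(20, 30), indB = c(40, 50)),
    mean_depth = 60, depth_dispersion = 0, stutter_prob = 0,
    low_mq_frac = 0, seed = 11L)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# memoized default small study (several test files reuse it)
.study_cache <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(.study_cache$study))
    .study_cache$study <- simulate_study(small_config())
  .study_cache$study
}

# single-interval coverage track
cov_track <- function(contig, start, end, depth) {
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(end), depth = as.integer(depth),
             stringsAsFactors = FALSE)
}

# bare variant-call rows
make_calls <- function(contig, pos, ref, alt, depth = 50, mq = 60,
                       gt = "0/1", sample_id = "s1") {
  n <- length(pos)
  data.frame(contig = rep_len(contig, n), pos = as.integer(pos),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             depth = as.integer(rep_len(depth, n)), mq = rep_len(mq, n),
             gt = rep_len(gt, n), sample_id = rep_len(sample_id, n),
             damaging = rep_len(FALSE, n), known = rep_len(FALSE, n),
             stringsAsFactors = FALSE)
}

# positionwise brute-force callable scan: positions with depth >= min in
# both tracks (independent oracle for callable_intersection)
brute_callable_positions <- function(cov_a, cov_b, min_depth, contig,
                                     max_pos) {
  ok <- function(cov, p) {
    d <- cov$depth[cov$contig == contig & cov$start <= p & cov$end > p]
    length(d) > 0 && any(d >= min_depth)
  }
  which(vapply(0:(max_pos - 1), function(p) ok(cov_a, p) && ok(cov_b, p),
               logical(1))) - 1L
}

# synthetic spanning reads for one locus: one read per requested observed
# repeat length, indel placed mid-tract (mirrors the aligned-read geometry
# the genotyper expects, built independently of the simulator)
make_msat_reads <- function(locus, observed_units, read_len = 100L,
                            offset = 20L) {
  mlen <- nchar(locus$motif)
  tract <- locus$end - locus$start
  rows <- lapply(seq_along(observed_units), function(i) {
    d_bp <- (observed_units[i] - locus$ref_repeat_count) * mlen
    ins_at <- offset + tract %/% 2L
    cigar <- if (d_bp == 0) paste0(read_len, "M")
    else if (d_bp > 0)
      paste0(ins_at, "M", d_bp, "I", read_len - ins_at - d_bp, "M")
    else paste0(ins_at, "M", -d_bp, "D", read_len - ins_at, "M")
    data.frame(qname = paste0("r", i), contig = locus$contig,
               pos = locus$start - offset + 1L, cigar = cigar,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

msat_locus <- function(contig = "ctg1", start = 1000L, motif = "AGC",
                       count = 8L) {
  data.frame(contig = contig, start = as.integer(start),
             end = as.integer(start + nchar(motif) * count), motif = motif,
             ref_repeat_count = as.integer(count),
             locus_id = paste0(contig, ":", start), stringsAsFactors = FALSE)
}
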