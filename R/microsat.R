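# Microsatellite genotyping from spanning reads and cross-timepoint
# comparison. A read is spanning when its aligned reference footprint covers
# the repeat tract plus a small flank with no clipping inside that window;
# the per-read repeat length is the reference tract length adjusted by the
# net indel length the read's CIGAR places within the tract.

.parse_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  list(lens = lens, ops = ops)
}

# reference bases consumed by an alignment
.ref_width <- function(cg) {
  sum(cg$lens[cg$ops %in% c("M", "D", "N", "=", "X")])
}

# repeat length (in units) a single read reports for a locus, or NA if the
# read does not span the tract + flank
.read_repeat_units <- function(pos0, cigar, locus, flank = 2L) {
  cg <- .parse_cigar(cigar)
  rw <- .ref_width(cg)
  if (pos0 > locus$start - flank || pos0 + rw < locus$end + flank)
    return(NA_real_)
  net <- 0L
  cursor <- pos0
  for (i in seq_along(cg$ops)) {
    op <- cg$ops[i]; len <- cg$lens[i]
    if (op %in% c("M", "=", "X")) {
      cursor <- cursor + len
    } else if (op %in% c("D", "N")) {
      ov <- max(0L, min(cursor + len, locus$end) - max(cursor, locus$start))
      net <- net - ov
      cursor <- cursor + len
    } else if (op == "I") {
      if (cursor >= locus$start && cursor <= locus$end) net <- net + len
    }
    # S/H/P consume neither reference nor tract
  }
  ((locus$end - locus$start) + net) / nchar(locus$motif)
}

#' Genotype one microsatellite locus from spanning reads
#'
#' Reads aligned to the locus contig whose reference footprint covers the
#' tract plus \code{flank} bp on each side are measured; allele lengths
#' supported by at least \code{min_allele_frac} of spanning reads survive,
#' and the top two (by read count, ties broken toward the shorter allele)
#' form the diploid genotype. Fewer than \code{min_spanning} spanning reads,
#' or no surviving allele, gives a no-call.
#'
#' @param reads data frame with contig, pos (1-based), cigar.
#' @param locus one catalog row (contig, start, end, motif,
#'   ref_repeat_count, locus_id).
#' @param min_spanning minimum spanning reads to call (default 15).
#' @param min_allele_frac minimum fraction of spanning reads supporting an
#'   allele (default 0.3).
#' @param flank bp beyond the tract a spanning read must cover (default 2).
#' @return one-row data frame: locus_id, a1, a2 (sorted repeat counts, NA
#'   if uncalled), n_spanning, called.
#' @export
genotype_locus <- function(reads, locus, min_spanning = 15,
                           min_allele_frac = 0.3, flank = 2L) {
  if (locus$start < 0L)
    stop("locus ", locus$locus_id, " outside reference bounds")
  sub <- reads[reads$contig == locus$contig, , drop = FALSE]
  units <- rep(NA_real_, nrow(sub))
  for (i in seq_len(nrow(sub)))
    units[i] <- .read_repeat_units(sub$pos[i] - 1L, sub$cigar[i], locus,
                                   flank)
  units <- units[!is.na(units)]
  n_spanning <- length(units)
  nocall <- data.frame(locus_id = locus$locus_id, a1 = NA_real_,
                       a2 = NA_real_, n_spanning = n_spanning,
                       called = FALSE, stringsAsFactors = FALSE)
  if (n_spanning < min_spanning) return(nocall)
  tab <- table(units)
  vals <- as.numeric(names(tab))
  cnt <- as.integer(tab)
  keep <- cnt >= min_allele_frac * n_spanning
  vals <- vals[keep]; cnt <- cnt[keep]
  if (!length(vals)) return(nocall)
  o <- order(-cnt, vals)   # by support desc, then shorter allele
  vals <- vals[o][seq_len(min(2L, length(vals)))]
  a <- sort(if (length(vals) == 1L) c(vals, vals) else vals)
  data.frame(locus_id = locus$locus_id, a1 = a[1L], a2 = a[2L],
             n_spanning = n_spanning, called = TRUE,
             stringsAsFactors = FALSE)
}

#' Genotype every catalog locus for one sample
#'
#' @param reads data frame of aligned reads (contig, pos, cigar).
#' @param catalog microsatellite catalog data frame.
#' @param ... passed to [genotype_locus()].
#' @return data frame, one row per locus.
#' @export
genotype_sample <- function(reads, catalog, ...) {
  rows <- lapply(seq_len(nrow(catalog)), function(k)
    genotype_locus(reads, catalog[k, ], ...))
  do.call(rbind, rows)
}

#' Compare two samples' microsatellite genotypes
#'
#' The denominator is the loci called in BOTH samples; a locus is variable
#' when the unordered allele pairs differ. The global microsatellite index
#' is 100 * variable / called-in-both. Frame status per variable locus is
#' the total repeat-length change times the motif length, modulo 3.
#'
#' @param gt_a,gt_b genotype data frames from [genotype_sample()] over the
#'   same catalog.
#' @param catalog the shared catalog (for motif lengths).
#' @return an \code{msat_comparison} list: n_called_both, variable (data
#'   frame), global_index (percent).
#' @export
compare_msat <- function(gt_a, gt_b, catalog) {
  if (!identical(gt_a$locus_id, gt_b$locus_id))
    stop("genotype tables come from different catalogs")
  both <- gt_a$called & gt_b$called
  n_both <- sum(both)
  ids <- gt_a$locus_id[both]
  a1 <- gt_a$a1[both]; a2 <- gt_a$a2[both]
  b1 <- gt_b$a1[both]; b2 <- gt_b$a2[both]
  differ <- a1 != b1 | a2 != b2
  mlen <- nchar(catalog$motif[match(ids, catalog$locus_id)])
  delta_units <- abs(b1 - a1) + abs(b2 - a2)
  variable <- data.frame(
    locus_id = ids[differ],
    a1_a = a1[differ], a2_a = a2[differ],
    a1_b = b1[differ], a2_b = b2[differ],
    frame_status = ifelse(
      (delta_units[differ] * mlen[differ]) %% 3 == 0,
      "nonframeshift", "frameshift"),
    stringsAsFactors = FALSE)
  structure(list(n_called_both = n_both, variable = variable,
                 n_variable = nrow(variable),
                 global_index = global_msat_index(nrow(variable), n_both)),
            class = "msat_comparison")
}

#' @export
print.msat_comparison <- function(x, ...) {
  cat("Microsatellite comparison\n")
  cat(sprintf("  called in both: %d\n", x$n_called_both))
  cat(sprintf("  variable: %d\n", x$n_variable))
  cat(sprintf("  global microsatellite index: %s%%\n",
              format_percent(x$global_index)))
  invisible(x)
}

#' Global microsatellite index (percent)
#'
#' 100 * variable loci / loci called in both samples.
#'
#' @param n_variable variable locus count.
#' @param n_called_both loci called in both samples.
#' @return percentage.
#' @export
global_msat_index <- function(n_variable, n_called_both) {
  if (n_called_both <= 0) {
    if (n_variable == 0) return(0)
    stop("n_called_both must be positive")
  }
  100 * n_variable / n_called_both
}

#' Microsatellite variation rate per locus per year
#'
#' @param n_variable variable loci.
#' @param n_called_both loci called in both samples.
#' @param years elapsed years between the samples.
#' @return rate in locus^-1 year^-1.
#' @export
msat_rate <- function(n_variable, n_called_both, years) {
  if (n_called_both <= 0) stop("n_called_both must be positive")
  if (years <= 0) stop("years must be positive")
  (n_variable / n_called_both) / years
}
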