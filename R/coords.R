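# Internal convention: all coordinates are 0-based half-open except at the VCF
# boundary (1-based). Variant identity is the normalized allele-level key
# (contig, pos, ref, alt).

#' Canonical (minimal-rotation) form of a repeat motif
#'
#' A repeat unit is reported in its canonical form: the lexicographically
#' smallest rotation of the unit. A motif equal to its canonical form is a
#' valid catalog unit; e.g. \code{"AGC"} is canonical while \code{"CAG"}
#' (a rotation of it) is not.
#'
#' @param motif character vector of repeat units (1-4 bp, ACGT).
#' @return character vector of canonical rotations.
#' @export
#' @examples
#' canonical_motif(c("CAG", "AGC", "A"))
canonical_motif <- function(motif) {
  vapply(motif, function(m) {
    n <- nchar(m)
    if (n == 0L) stop("empty motif")
    rots <- vapply(seq_len(n), function(i) {
      paste0(substr(m, i, n), substr(m, 1, i - 1L))
    }, character(1))
    min(rots)
  }, character(1), USE.NAMES = FALSE)
}

#' Allele-level variant keys
#'
#' @param calls variant-call data frame with columns contig, pos, ref, alt.
#' @return character vector "contig:pos:ref:alt".
#' @export
variant_key <- function(calls) {
  paste(calls$contig, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Normalize variant representations
#'
#' Trims shared suffix then prefix bases (keeping a 1 bp anchor for indels)
#' and left-aligns indels against the reference, producing the minimal
#' left-aligned representation used for cross-sample key comparison.
#'
#' @param calls variant-call data frame (1-based \code{pos}).
#' @param reference named character vector (or DNAStringSet) of contig
#'   sequences; required to left-align indels.
#' @return the data frame with pos/ref/alt rewritten in normalized form.
#' @export
normalize_variants <- function(calls, reference = NULL) {
  if (nrow(calls) == 0L) return(calls)
  refseq <- .as_ref_chr(reference)
  for (i in seq_len(nrow(calls))) {
    v <- .normalize_one(calls$contig[i], calls$pos[i], calls$ref[i],
                        calls$alt[i], refseq)
    calls$pos[i] <- v$pos
    calls$ref[i] <- v$ref
    calls$alt[i] <- v$alt
  }
  calls
}

.as_ref_chr <- function(reference) {
  if (is.null(reference)) return(NULL)
  if (methods::is(reference, "DNAStringSet")) {
    stats::setNames(as.character(reference), names(reference))
  } else {
    reference
  }
}

.normalize_one <- function(contig, pos, ref, alt, refseq) {
  # trim common suffix
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) ==
         substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim common prefix, keeping one anchor base when lengths differ
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  # left-align pure indels when the reference is available: while both
  # alleles end in the same base, drop it and prepend the previous
  # reference base
  if (!is.null(refseq) && nchar(ref) != nchar(alt) &&
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    seq <- refseq[[contig]]
    repeat {
      if (pos <= 1L) break
      if (substr(ref, nchar(ref), nchar(ref)) !=
          substr(alt, nchar(alt), nchar(alt))) break
      prev <- substr(seq, pos - 1L, pos - 1L)
      ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
      alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
      pos <- pos - 1L
    }
    # re-trim any shared prefix uncovered by the shift
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
           substr(ref, 2L, 2L) == substr(alt, 2L, 2L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
  }
  list(pos = pos, ref = ref, alt = alt)
}

# interval helpers on (start, end) 0-based half-open matrices/data frames

.intervals_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.granges_to_intervals <- function(gr) {
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}
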