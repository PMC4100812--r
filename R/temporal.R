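# Core temporal comparison: quality filtering, the callable intersection of
# two samples' coverage, and the acquired/lost/persistent partition of their
# variant sets.

#' Quality-filter parameters
#'
#' Depth is compared inclusively (kept when depth >= min_depth); mapping
#' quality strictly (kept when MQ > min_mq). min_verify_reads is the
#' read-support threshold a locus must meet in BOTH samples to be callable.
#'
#' @param min_depth minimum read depth (default 5, inclusive).
#' @param min_mq minimum mapping quality (default 30, strict >).
#' @param min_verify_reads minimum supporting reads in both comparison
#'   samples (default 5).
#' @return a \code{filter_params} list.
#' @export
filter_params <- function(min_depth = 5, min_mq = 30, min_verify_reads = 5) {
  stopifnot(min_depth >= 0, min_mq >= 0, min_verify_reads >= 0)
  structure(list(min_depth = min_depth, min_mq = min_mq,
                 min_verify_reads = min_verify_reads),
            class = "filter_params")
}

#' Filter variant calls on depth and mapping quality
#'
#' Keeps calls with \code{depth >= min_depth} and \code{mq > min_mq};
#' input order is preserved. Counts of removed calls by reason are attached
#' as attribute \code{removed}.
#'
#' @param calls variant-call data frame.
#' @param params a [filter_params()].
#' @return the filtered data frame.
#' @export
filter_calls <- function(calls, params = filter_params()) {
  if (nrow(calls) == 0L) {
    attr(calls, "removed") <- c(low_depth = 0L, low_mq = 0L)
    return(calls)
  }
  low_depth <- calls$depth < params$min_depth
  low_mq <- calls$mq <= params$min_mq
  out <- calls[!(low_depth | low_mq), , drop = FALSE]
  attr(out, "removed") <- c(low_depth = sum(low_depth & !low_mq),
                            low_mq = sum(low_mq))
  out
}

#' Callable intersection of two coverage tracks
#'
#' Positions covered by at least \code{min_depth} reads in BOTH tracks.
#'
#' @param cov_a,cov_b coverage data frames (contig, start, end, depth).
#' @param min_depth depth threshold (inclusive).
#' @return list with \code{intervals} (sorted, disjoint, merged data frame)
#'   and \code{callable_bp}.
#' @export
callable_intersection <- function(cov_a, cov_b, min_depth = 5) {
  ga <- .callable_granges(cov_a, min_depth)
  gb <- .callable_granges(cov_b, min_depth)
  gi <- GenomicRanges::intersect(ga, gb)
  iv <- .granges_to_intervals(gi)
  list(intervals = iv, callable_bp = sum(iv$end - iv$start))
}

.callable_granges <- function(cov, min_depth) {
  keep <- cov[cov$depth >= min_depth, , drop = FALSE]
  if (!nrow(keep)) return(GenomicRanges::GRanges())
  GenomicRanges::reduce(.intervals_to_granges(keep))
}

#' Bundle one sample's calls and coverage
#'
#' @param sample_id identifier.
#' @param age sampling age (years).
#' @param calls variant-call data frame.
#' @param coverage coverage data frame.
#' @return an \code{exome_sample} list.
#' @export
exome_sample <- function(sample_id, age, calls, coverage) {
  structure(list(sample_id = sample_id, age = age, calls = calls,
                 coverage = coverage), class = "exome_sample")
}

# TRUE where the variant's whole reference footprint lies inside the
# callable intervals (SNVs: the single base; indels: every base of the
# reference allele footprint)
.keys_callable <- function(calls, intervals) {
  if (nrow(calls) == 0L) return(logical(0))
  vapply(seq_len(nrow(calls)), function(i) {
    s <- calls$pos[i] - 1L
    e <- s + nchar(calls$ref[i])
    sub <- intervals[intervals$contig == calls$contig[i] &
                       intervals$start < e & intervals$end > s, ,
                     drop = FALSE]
    if (!nrow(sub)) return(FALSE)
    # footprint must be fully inside one merged interval
    any(sub$start <= s & sub$end >= e)
  }, logical(1))
}

#' Partition two time points' variants into acquired / lost / persistent
#'
#' Both samples are quality-filtered, the callable intersection of their
#' coverage (at \code{min_verify_reads}) is computed, variant sets are
#' restricted to it, and the partition is taken by normalized allele-level
#' key: acquired = later minus earlier, lost = earlier minus later,
#' persistent = intersection. Keys whose footprint is not callable in both
#' samples are excluded from all three sets and reported as unverifiable.
#'
#' @param earlier,later \code{exome_sample} objects from the same
#'   individual; \code{later$age} must exceed \code{earlier$age}.
#' @param params a [filter_params()].
#' @param count_genotype_changes if TRUE, variants present at both time
#'   points whose genotype string differs are counted as differing
#'   (reported in \code{genotype_changed}) rather than persistent.
#' @return a \code{temporal_diff} object.
#' @export
diff_timepoints <- function(earlier, later, params = filter_params(),
                            count_genotype_changes = FALSE) {
  if (identical(earlier$sample_id, later$sample_id))
    stop("earlier and later are the same sample: ", earlier$sample_id)
  if (!is.null(earlier$age) && !is.null(later$age) &&
      later$age <= earlier$age)
    stop("later sample must have greater age than earlier sample")
  fa <- filter_calls(earlier$calls, params)
  fb <- filter_calls(later$calls, params)
  cal <- callable_intersection(earlier$coverage, later$coverage,
                               params$min_verify_reads)
  ka <- variant_key(fa); kb <- variant_key(fb)
  ca <- .keys_callable(fa, cal$intervals)
  cb <- .keys_callable(fb, cal$intervals)
  unverifiable <- union(ka[!ca], kb[!cb])
  ka_c <- setdiff(ka[ca], unverifiable)
  kb_c <- setdiff(kb[cb], unverifiable)
  acquired <- setdiff(kb_c, ka_c)
  lost <- setdiff(ka_c, kb_c)
  persistent <- intersect(ka_c, kb_c)
  genotype_changed <- character(0)
  if (count_genotype_changes && length(persistent)) {
    gta <- fa$gt[match(persistent, ka)]
    gtb <- fb$gt[match(persistent, kb)]
    genotype_changed <- persistent[gta != gtb]
    persistent <- setdiff(persistent, genotype_changed)
  }
  union_n <- length(acquired) + length(lost) + length(persistent) +
    length(genotype_changed)
  structure(list(
    individual_id = sub("_y[0-9.]+$", "", earlier$sample_id),
    earlier_age = earlier$age, later_age = later$age,
    acquired = sort(acquired), lost = sort(lost),
    persistent = sort(persistent),
    genotype_changed = sort(genotype_changed),
    unverifiable = sort(unverifiable),
    callable_bp = cal$callable_bp,
    callable_intervals = cal$intervals,
    n_differing = length(acquired) + length(lost) +
      length(genotype_changed),
    shared_fraction = if (union_n == 0L) 1 else
      length(persistent) / union_n
  ), class = "temporal_diff")
}

#' @export
print.temporal_diff <- function(x, ...) {
  cat("Temporal exome comparison:", x$individual_id, "\n")
  cat(sprintf("  ages %s -> %s (%s years apart)\n", x$earlier_age,
              x$later_age, x$later_age - x$earlier_age))
  cat(sprintf("  callable: %d bp\n", x$callable_bp))
  cat(sprintf("  acquired %d | lost %d | persistent %d | unverifiable %d\n",
              length(x$acquired), length(x$lost), length(x$persistent),
              length(x$unverifiable)))
  cat(sprintf("  differing %d, shared fraction %.3f\n", x$n_differing,
              x$shared_fraction))
  invisible(x)
}

#' Baseline-anchored comparisons across a time series
#'
#' Computes [diff_timepoints()] between the earliest sample and each later
#' sample (not consecutive pairs), so a variant acquired and then lost is
#' reported acquired in the first comparison and absent from later ones.
#'
#' @param samples list of \code{exome_sample} objects, ages strictly
#'   increasing.
#' @param params a [filter_params()].
#' @param ... passed to [diff_timepoints()].
#' @return list of \code{temporal_diff} objects, one per later sample.
#' @export
multi_timepoint_series <- function(samples, params = filter_params(), ...) {
  if (length(samples) < 2L)
    stop("need at least 2 samples for a time series")
  ages <- vapply(samples, `[[`, numeric(1), "age")
  if (any(diff(ages) <= 0)) stop("sample ages must be strictly increasing")
  baseline <- samples[[1L]]
  lapply(samples[-1L], function(s)
    diff_timepoints(baseline, s, params, ...))
}

#' Export a temporal comparison as a status table
#'
#' @param diff a \code{temporal_diff}.
#' @return data frame with columns key and status (acquired, lost,
#'   persistent, unverifiable).
#' @export
diff_table <- function(diff) {
  data.frame(
    key = c(diff$acquired, diff$lost, diff$persistent, diff$unverifiable),
    status = rep(c("acquired", "lost", "persistent", "unverifiable"),
                 c(length(diff$acquired), length(diff$lost),
                   length(diff$persistent), length(diff$unverifiable))),
    stringsAsFactors = FALSE)
}
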