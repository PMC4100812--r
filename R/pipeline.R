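# End-to-end orchestration: load a study bundle from disk, run the temporal
# comparisons, annotation, microsatellite analysis, rate statistics and
# (optionally) enrichment, and emit TSV tables plus a plain-text summary.

#' Pipeline run configuration
#'
#' @param dir directory holding a study bundle (as written by
#'   [write_simulated_study()]: reference.fa, genes.gff3, targets.bed,
#'   msat_catalog.tsv, samples.tsv manifest, per-sample VCF/coverage/SAM).
#' @param out_dir output directory for report tables.
#' @param min_depth,min_mq,min_verify_reads see [filter_params()].
#' @param min_spanning,min_allele_frac see [genotype_locus()].
#' @param target_bp denominator for per-bp rates; \code{"callable"} uses
#'   each comparison's measured callable width (the statistically honest
#'   choice), a number uses that fixed target size.
#' @param known path to a known-variant catalog TSV (optional; defaults to
#'   \code{known_variants.tsv} in \code{dir} when present).
#' @param gmt path to a GMT-like term annotation for enrichment (optional).
#' @param alpha significance level for the Bonferroni-corrected p-value.
#' @return a \code{run_config} list.
#' @export
run_config <- function(dir, out_dir = file.path(dir, "report"),
                       min_depth = 5, min_mq = 30, min_verify_reads = 5,
                       min_spanning = 15, min_allele_frac = 0.3,
                       target_bp = "callable", known = NULL, gmt = NULL,
                       alpha = 0.05) {
  structure(list(dir = dir, out_dir = out_dir, min_depth = min_depth,
                 min_mq = min_mq, min_verify_reads = min_verify_reads,
                 min_spanning = min_spanning,
                 min_allele_frac = min_allele_frac, target_bp = target_bp,
                 known = known, gmt = gmt, alpha = alpha),
            class = "run_config")
}

.require_file <- function(path, what) {
  if (!file.exists(path))
    stop(what, " file not found: ", path)
  path
}

#' Run the full serial-exome pipeline on a study bundle
#'
#' Stages: load inputs; per individual, baseline-anchored temporal diffs;
#' functional annotation of differing variants; microsatellite genotyping
#' and comparison; rate statistics; gene recurrence and (if term
#' annotations and damaging flags are available) Fisher/Bonferroni
#' enrichment. Every emitted number is traceable to an intermediate TSV;
#' the run is deterministic given its inputs.
#'
#' @param config a [run_config()].
#' @return a \code{pipeline_report} list of all result tables, invisibly
#'   written to \code{config$out_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir <- config$dir
  reference <- read_reference_fasta(.require_file(
    file.path(dir, "reference.fa"), "reference"))
  genes <- read_gene_models(.require_file(
    file.path(dir, "genes.gff3"), "gene model"))
  catalog <- read_msat_catalog(.require_file(
    file.path(dir, "msat_catalog.tsv"), "microsatellite catalog"))
  manifest <- utils::read.delim(.require_file(
    file.path(dir, "samples.tsv"), "sample manifest"),
    stringsAsFactors = FALSE)
  known_keys <- NULL
  known_path <- config$known %||% file.path(dir, "known_variants.tsv")
  if (file.exists(known_path)) known_keys <- read_known_catalog(known_path)
  params <- filter_params(config$min_depth, config$min_mq,
                          config$min_verify_reads)

  samples <- list()
  msat_gt <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    calls <- read_vcf(.require_file(file.path(dir, row$vcf), "VCF"),
                      sample_id = row$sample_id)
    cov <- read_coverage(.require_file(file.path(dir, row$coverage),
                                       "coverage"))
    samples[[row$sample_id]] <- exome_sample(row$sample_id, row$age, calls,
                                             cov)
    reads <- read_sam_reads(.require_file(file.path(dir, row$reads),
                                          "spanning reads"))
    msat_gt[[row$sample_id]] <- genotype_sample(
      reads, catalog, min_spanning = config$min_spanning,
      min_allele_frac = config$min_allele_frac)
  }

  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  individuals <- unique(manifest$individual)
  diff_rows <- list(); rate_rows <- list(); msat_rows <- list()
  class_tab <- list(); gene_maps <- list(); damaged <- list()
  all_ann <- list()
  for (ind in individuals) {
    sub <- manifest[manifest$individual == ind, , drop = FALSE]
    sub <- sub[order(sub$age), , drop = FALSE]
    if (nrow(sub) < 2L) next
    series <- multi_timepoint_series(
      lapply(sub$sample_id, function(s) samples[[s]]), params)
    base_id <- sub$sample_id[1L]
    for (j in seq_along(series)) {
      d <- series[[j]]
      later_id <- sub$sample_id[j + 1L]
      cmp <- paste0(ind, "_", d$earlier_age, "v", d$later_age)
      utils::write.table(
        diff_table(d),
        file.path(config$out_dir, paste0("diff_", cmp, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      differing <- c(d$acquired, d$lost)
      vc <- .keys_to_calls(differing, samples, c(later_id, base_id))
      ann <- classify_variants(vc, genes, reference, known_keys)
      all_ann[[cmp]] <- ann
      utils::write.table(
        ann, file.path(config$out_dir, paste0("annot_", cmp, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      cc <- class_counts(ann)
      wc <- worst_consequence(ann)
      n_ns <- sum(wc$class == "nonsynonymous")
      years <- d$later_age - d$earlier_age
      denom <- if (identical(config$target_bp, "callable"))
        d$callable_bp else config$target_bp
      class_tab[[cmp]] <- c(total_differing = d$n_differing, cc,
                            novel_nssnv = sum(wc$class == "nonsynonymous" &
                              isTRUE_vec(ann$novel[match(wc$key, ann$key)])))
      rate_rows[[cmp]] <- data.frame(
        comparison = cmp, individual = ind, years = years,
        n_differing = d$n_differing, n_nssnv = n_ns,
        callable_bp = d$callable_bp, denominator_bp = denom,
        nssnv_rate = nssnv_rate(n_ns, denom, years),
        shared_fraction = d$shared_fraction, stringsAsFactors = FALSE)

      mc <- compare_msat(msat_gt[[base_id]], msat_gt[[later_id]], catalog)
      loc <- if ("location" %in% names(catalog))
        catalog$location[match(mc$variable$locus_id, catalog$locus_id)]
      else vapply(mc$variable$locus_id, function(id) {
        k <- match(id, catalog$locus_id)
        locate_feature(catalog$contig[k], catalog$start[k],
                       catalog$end[k], genes)$class
      }, character(1))
      msat_rows[[cmp]] <- data.frame(
        comparison = cmp, individual = ind, years = years,
        n_called_both = mc$n_called_both, n_variable = mc$n_variable,
        global_index = mc$global_index,
        msat_rate = if (mc$n_called_both > 0)
          msat_rate(mc$n_variable, mc$n_called_both, years) else NA_real_,
        n_exonic_variable = sum(loc == "exonic"),
        n_nonframeshift = sum(mc$variable$frame_status == "nonframeshift"),
        stringsAsFactors = FALSE)
    }
    # gene recurrence over all differing variants vs baseline (last diff
    # spans the full study interval; union over diffs captures transients)
    ind_ann <- do.call(rbind, all_ann[grep(paste0("^", ind, "_"),
                                           names(all_ann))])
    gene_maps[[ind]] <- gene_mutation_counts(ind_ann)
    damaged[[ind]] <- tryCatch(damaged_gene_set(ind_ann),
                               error = function(e) character(0))
  }

  rates <- do.call(rbind, rate_rows)
  msat_summary <- do.call(rbind, msat_rows)
  utils::write.table(rates, file.path(config$out_dir, "rates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(msat_summary,
                     file.path(config$out_dir, "msat_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cls <- .class_count_table(class_tab)
  utils::write.table(cls, file.path(config$out_dir, "class_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  top_genes <- if (length(gene_maps) >= 2L)
    top_gene_intersection(gene_maps, k = 100) else NULL
  if (!is.null(top_genes))
    utils::write.table(top_genes,
                       file.path(config$out_dir, "top_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  enrichment <- NULL
  if (!is.null(config$gmt)) {
    term_map <- read_term_annotation(.require_file(config$gmt,
                                                   "term annotation"))
    universe <- .target_universe(genes)
    enr_rows <- list()
    for (ind in names(damaged)) {
      dg <- intersect(damaged[[ind]], universe)
      if (!length(dg)) next
      er <- fisher_enrichment(dg, universe, term_map, config$alpha)
      er$individual <- ind
      enr_rows[[ind]] <- er
    }
    if (length(enr_rows)) {
      enrichment <- do.call(rbind, enr_rows)
      utils::write.table(enrichment,
                         file.path(config$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  report <- list(rates = rates, msat_summary = msat_summary,
                 class_counts = cls, top_genes = top_genes,
                 enrichment = enrichment, gene_maps = gene_maps,
                 damaged = damaged, annotations = all_ann,
                 config = config)
  class(report) <- "pipeline_report"
  .write_summary(report, file.path(config$out_dir, "summary.txt"))
  report
}

# universe of genes overlapping the target space: with the bundle's gene
# models all genes are targeted, so the universe is all modelled genes
.target_universe <- function(genes) {
  sort(vapply(genes, `[[`, character(1), "gene_name"))
}

.keys_to_calls <- function(keys, samples, prefer_ids) {
  if (!length(keys))
    return(.empty_calls("diff"))
  rows <- list()
  for (key in keys) {
    found <- NULL
    for (sid in prefer_ids) {
      calls <- samples[[sid]]$calls
      hit <- which(variant_key(calls) == key)
      if (length(hit)) { found <- calls[hit[1L], ]; break }
    }
    if (!is.null(found)) rows[[length(rows) + 1L]] <- found
  }
  do.call(rbind, rows)
}

.class_count_table <- function(class_tab) {
  if (!length(class_tab)) return(data.frame())
  all_names <- unique(unlist(lapply(class_tab, names)))
  m <- t(vapply(class_tab, function(x) {
    out <- stats::setNames(rep(0L, length(all_names)), all_names)
    out[names(x)] <- as.integer(x)
    out
  }, integer(length(all_names))))
  data.frame(comparison = names(class_tab), m, stringsAsFactors = FALSE,
             check.names = FALSE)
}

.write_summary <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("Serial-exome analysis summary")
  w("=============================")
  cfg <- report$config
  w("thresholds: min depth >=%s, MQ >%s, verify reads >=%s in both samples,",
    cfg$min_depth, cfg$min_mq, cfg$min_verify_reads)
  w("            min spanning reads %s, allele fraction %s",
    cfg$min_spanning, cfg$min_allele_frac)
  w("")
  for (i in seq_len(nrow(report$rates))) {
    r <- report$rates[i, ]
    w("%s: %d differing variants over %d callable bp in %s years",
      r$comparison, r$n_differing, r$callable_bp, format(r$years))
    w("  nsSNV rate: %s bp^-1 year^-1 (%d nsSNVs / %s bp / %s years)",
      format(format_rate(r$nssnv_rate)), r$n_nssnv,
      format(r$denominator_bp), format(r$years))
    m <- report$msat_summary[report$msat_summary$comparison ==
                               r$comparison, ]
    if (nrow(m))
      w("  microsatellites: %d called in both, %d variable, index %s%%",
        m$n_called_both, m$n_variable, format_percent(m$global_index))
  }
  if (!is.null(report$top_genes) && nrow(report$top_genes)) {
    w("")
    w("recurrently mutated genes shared across individuals: %d",
      nrow(report$top_genes))
  }
  if (!is.null(report$enrichment)) {
    w("")
    w("enrichment terms significant after Bonferroni: %d",
      sum(report$enrichment$significant))
  }
  invisible(path)
}

#' Recompute the worked-example statistics from their published inputs
#'
#' Each headline rate and index whose inputs (counts, target size, elapsed
#' years) are themselves reported can be recomputed exactly; this check
#' table recomputes every one and compares it, after the report rounding
#' conventions, with its expected printed value.
#'
#' @return data frame: statistic, inputs, computed, expected, match.
#' @export
verify_worked_examples <- function() {
  rows <- list(
    list("nsSNV rate, individual-2 (16 y)",
         "8398 nsSNVs / 62.2 Mb / 16 y",
         format_rate(nssnv_rate(8398, 62.2e6, 16)), 8.4e-6),
    list("nsSNV rate, individual-3 (15 y)",
         "901 nsSNVs / 62.2 Mb / 15 y",
         format_rate(nssnv_rate(901, 62.2e6, 15)), 9.6e-7),
    list("microsatellite rate, individual-1 (13 y)",
         "173 variable / 53161 called / 13 y",
         format_rate(msat_rate(173, 53161, 13)), 2.5e-4),
    list("microsatellite rate, individual-2 (16 y)",
         "801 variable / 49988 called / 16 y",
         format_rate(msat_rate(801, 49988, 16)), 1.0e-3),
    list("global microsatellite index, individual-1",
         "173 / 53161",
         as.numeric(format_percent(global_msat_index(173, 53161))), 0.3),
    list("global microsatellite index, individual-2",
         "801 / 49988",
         as.numeric(format_percent(global_msat_index(801, 49988))), 1.6),
    list("exonic variable microsatellites, all individuals",
         "4 + 26 + 1 + 2", 4 + 26 + 1 + 2, 33)
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(statistic = r[[1]], inputs = r[[2]], computed = r[[3]],
               expected = r[[4]], stringsAsFactors = FALSE)))
  out$match <- out$computed == out$expected
  out
}
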