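# Rate statistics, recurrently-mutated-gene ranking across individuals, and
# Fisher/Bonferroni gene-set enrichment.

#' Nonsynonymous SNV variation rate per bp per year
#'
#' @param n_nssnv count of differing nonsynonymous SNVs between the two
#'   time points.
#' @param target_bp target sequence size in bp (default 62.2 Mb, the
#'   standard exome target used throughout the report tables).
#' @param years elapsed years.
#' @return exact rate in bp^-1 year^-1 (format with [format_rate()] for
#'   reporting).
#' @export
nssnv_rate <- function(n_nssnv, target_bp = 62.2e6, years) {
  if (target_bp <= 0) stop("target_bp must be positive")
  if (years <= 0) stop("years must be positive")
  if (n_nssnv < 0) stop("n_nssnv must be >= 0")
  n_nssnv / (target_bp * years)
}

#' Report a rate at 2 significant figures (report convention)
#'
#' Truncates toward zero at the second significant digit. Truncation, not
#' half-up rounding, is the convention the report tables use: it reproduces
#' every printed headline rate from its printed inputs (e.g. 901 nsSNVs /
#' 62.2 Mb / 15 y = 9.657e-7, printed as 9.6e-7).
#'
#' @param x numeric rate.
#' @export
format_rate <- function(x) {
  vapply(x, function(v) {
    if (!is.finite(v) || v == 0) return(v)
    s <- sign(v); a <- abs(v)
    e <- floor(log10(a))
    s * trunc(a / 10^(e - 1L) + 1e-9) / 10 * 10^e
  }, numeric(1))
}

#' Format a percentage with 1 decimal place (report convention)
#' @param x numeric percentage.
#' @export
format_percent <- function(x) sprintf("%.1f", x)

#' Per-gene counts of differing variants
#'
#' Counts distinct variants per gene from an annotation table; a variant
#' annotated against several genes counts once for each gene.
#'
#' @param annotations data frame with key and gene columns (as from
#'   [classify_variants()]); rows with missing gene are ignored.
#' @return named integer vector, gene -> count.
#' @export
gene_mutation_counts <- function(annotations) {
  ann <- annotations[!is.na(annotations$gene), , drop = FALSE]
  ann <- ann[!duplicated(ann[, c("key", "gene")]), , drop = FALSE]
  if (!nrow(ann)) return(stats::setNames(integer(0), character(0)))
  tab <- table(ann$gene)
  stats::setNames(as.integer(tab), names(tab))
}

#' Intersection of the top-k most mutated genes across individuals
#'
#' Each individual contributes its k highest-count genes (all genes tied
#' with the k-th count are included); the returned table is the
#' intersection, with each individual's count.
#'
#' @param maps named list of gene->count vectors, one per individual.
#' @param k list depth (default 100).
#' @return data frame: gene, then one count column per individual, sorted
#'   by total count decreasing.
#' @export
top_gene_intersection <- function(maps, k = 100) {
  if (k < 1) stop("k must be >= 1")
  if (length(maps) < 2L) stop("need at least 2 individuals")
  top_sets <- lapply(maps, function(m) {
    if (!length(m)) return(character(0))
    o <- order(-m, names(m))
    m <- m[o]
    if (length(m) <= k) return(names(m))
    cutoff <- m[[k]]
    names(m)[m >= cutoff]
  })
  common <- Reduce(intersect, top_sets)
  out <- data.frame(gene = common, stringsAsFactors = FALSE)
  for (ind in names(maps))
    out[[ind]] <- unname(maps[[ind]][common])
  if (nrow(out)) {
    tot <- rowSums(as.matrix(out[, -1L, drop = FALSE]))
    out <- out[order(-tot, out$gene), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Fisher's exact gene-set enrichment with Bonferroni correction
#'
#' One-sided (over-representation) Fisher's exact test of each term's gene
#' set against the gene universe; p-values are Bonferroni-corrected over
#' the number of terms actually tested (terms with at least one universe
#' gene) and flagged significant below \code{alpha}.
#'
#' @param gene_set character vector of genes of interest (subset of
#'   \code{universe}).
#' @param universe character vector of all observable genes.
#' @param term_map named list term -> gene vector (e.g. from
#'   [read_term_annotation()]).
#' @param alpha significance level for the corrected p-value (default 0.05).
#' @return data frame term, k, K, n, N, p_value, p_bonferroni, significant,
#'   sorted by p_value.
#' @export
fisher_enrichment <- function(gene_set, universe, term_map, alpha = 0.05) {
  gene_set <- unique(gene_set); universe <- unique(universe)
  if (!all(gene_set %in% universe))
    stop("gene_set contains genes absent from the universe: ",
         paste(utils::head(setdiff(gene_set, universe), 3), collapse = ", "))
  N <- length(universe); n <- length(gene_set)
  sets <- lapply(term_map, function(g) intersect(unique(g), universe))
  tested <- names(sets)[vapply(sets, length, integer(1)) > 0L]
  rows <- lapply(tested, function(term) {
    term_genes <- sets[[term]]
    K <- length(term_genes)
    k <- length(intersect(term_genes, gene_set))
    tab <- matrix(c(k, n - k, K - k, N - n - K + k), nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(term = term, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(term = character(), k = integer(), K = integer(),
               n = integer(), N = integer(), p_value = numeric(),
               stringsAsFactors = FALSE)
  out$p_bonferroni <- pmin(1, out$p_value * length(tested))
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Genes carrying at least one damaging-flagged variant
#'
#' @param annotations annotation data frame with gene and damaging columns.
#' @return character vector of gene names.
#' @export
damaged_gene_set <- function(annotations) {
  if (!nrow(annotations) || all(is.na(annotations$damaging)))
    stop("damaging flags are not populated; supply DMG annotations ",
         "(VCF INFO DMG=1 or a sidecar table)")
  hit <- isTRUE_vec(annotations$damaging) & !is.na(annotations$gene)
  sort(unique(annotations$gene[hit]))
}
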