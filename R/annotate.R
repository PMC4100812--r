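# Functional classification of variants against gene models and the
# reference: coding consequences by codon translation (strand-aware,
# standard genetic code), frameshift parity for indels, splice-adjacency
# within 2 bp of an intron/exon junction, and positional classes
# (UTR exon/intron, intronic, up/downstream within 1 kb, intergenic).

# worst-consequence first
.SEVERITY <- c("stop_gain", "stop_loss", "frameshift_indel", "splicing",
               "nonsynonymous", "nonframeshift_indel", "synonymous",
               "utr5_exon", "utr3_exon", "utr5_intron", "utr3_intron",
               "intronic", "upstream", "downstream", "intergenic",
               "exonic")

#' Severity ranking of functional classes
#'
#' Lower rank means a more severe consequence; used to pick the
#' worst-consequence class when a variant overlaps several features.
#'
#' @param class character vector of class names.
#' @return integer ranks.
#' @export
class_severity <- function(class) match(class, .SEVERITY)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.revcomp <- function(s) {
  paste(rev(.COMPLEMENT[strsplit(s, "")[[1L]]]), collapse = "")
}

# spliced CDS sequence (transcript orientation) and a map from genomic pos0
# to transcript index
.spliced_cds <- function(model, reference) {
  refseq <- .as_ref_chr(reference)
  cds <- cds_intervals(model)
  pieces <- vapply(seq_len(nrow(cds)), function(i)
    substr(refseq[[model$contig]], cds[i, 1L] + 1L, cds[i, 2L]),
    character(1))
  genomic <- paste(pieces, collapse = "")
  tx <- if (model$strand == "+") genomic else .revcomp(genomic)
  list(cds = cds, tx = tx, len = nchar(genomic))
}

.tx_index <- function(pos0, sc, strand) {
  # genomic-order offset of pos0 within the concatenated CDS pieces
  g <- 0L
  for (i in seq_len(nrow(sc$cds))) {
    s <- sc$cds[i, 1L]; e <- sc$cds[i, 2L]
    if (pos0 >= s && pos0 < e) {
      g <- g + (pos0 - s)
      if (strand == "+") return(g) else return(sc$len - 1L - g)
    }
    g <- g + (e - s)
  }
  NA_integer_
}

.in_intervals <- function(pos0, iv) {
  any(iv[, 1L] <= pos0 & pos0 < iv[, 2L])
}

#' Classify a single-nucleotide substitution against one gene model
#'
#' Inside the CDS the affected codon is translated on both alleles
#' (strand-aware, standard genetic code): same amino acid is synonymous,
#' non-stop to stop is stop_gain, stop to non-stop is stop_loss, anything
#' else nonsynonymous. Intronic positions within 2 bp of an exon boundary
#' are splicing; other positions get their location class.
#'
#' @param variant one-row variant data frame (or list) with contig, pos
#'   (1-based), ref, alt; ref and alt must be single bases.
#' @param model a \code{gene_model} on the same contig.
#' @param reference named character vector (or DNAStringSet) of contigs.
#' @return a class string.
#' @export
classify_snv <- function(variant, model, reference) {
  stopifnot(nchar(variant$ref) == 1L, nchar(variant$alt) == 1L)
  refseq <- .as_ref_chr(reference)
  pos0 <- variant$pos - 1L
  obs <- substr(refseq[[variant$contig]], variant$pos, variant$pos)
  if (obs != variant$ref)
    stop("reference mismatch at ", variant$contig, ":", variant$pos,
         ": reference has ", obs, ", call says ", variant$ref)
  cds <- cds_intervals(model)
  if (nrow(cds) && .in_intervals(pos0, cds)) {
    sc <- .spliced_cds(model, refseq)
    t <- .tx_index(pos0, sc, model$strand)
    codon_i <- t %/% 3L
    within <- t %% 3L
    ref_codon <- substr(sc$tx, codon_i * 3L + 1L, codon_i * 3L + 3L)
    alt_base <- if (model$strand == "+") variant$alt else
      .COMPLEMENT[[variant$alt]]
    alt_codon <- ref_codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_base
    aa_ref <- as.character(Biostrings::GENETIC_CODE[ref_codon])
    aa_alt <- as.character(Biostrings::GENETIC_CODE[alt_codon])
    if (aa_ref == aa_alt) return("synonymous")
    if (aa_ref != "*" && aa_alt == "*") return("stop_gain")
    if (aa_ref == "*" && aa_alt != "*") return("stop_loss")
    return("nonsynonymous")
  }
  .positional_class(pos0, pos0 + 1L, model)
}

#' Classify an insertion or deletion against one gene model
#'
#' The CDS-overlapping inserted/deleted length decides frame parity:
#' frameshift_indel when not divisible by 3, nonframeshift_indel otherwise.
#' Indels not touching the CDS get their location class.
#'
#' @param variant one-row variant data frame (anchored VCF representation).
#' @param model a \code{gene_model}.
#' @return a class string.
#' @export
classify_indel <- function(variant, model) {
  rlen <- nchar(variant$ref); alen <- nchar(variant$alt)
  stopifnot(rlen != alen)
  pos0 <- variant$pos - 1L
  cds <- cds_intervals(model)
  if (rlen > alen) {
    # deletion: deleted bases follow the anchor
    ds <- pos0 + alen; de <- pos0 + rlen
    dl <- 0L
    for (i in seq_len(nrow(cds)))
      dl <- dl + max(0L, min(de, cds[i, 2L]) - max(ds, cds[i, 1L]))
    if (dl > 0L)
      return(if (dl %% 3L != 0L) "frameshift_indel" else
               "nonframeshift_indel")
    return(.positional_class(pos0, de, model))
  }
  # insertion: inserted bases sit in the gap after the anchor base
  gap <- pos0 + 1L
  inside <- any(cds[, 1L] < gap & gap < cds[, 2L])
  if (nrow(cds) && inside) {
    il <- alen - rlen
    return(if (il %% 3L != 0L) "frameshift_indel" else
             "nonframeshift_indel")
  }
  .positional_class(pos0, pos0 + 1L, model)
}

# location class of interval [s, e) relative to one gene model; precedence
# CDS exon > UTR exon > splicing-adjacent > UTR intron > intronic >
# up/downstream (1 kb) > intergenic
.positional_class <- function(s, e, model, window = 1000L,
                              splice_bp = 2L) {
  g0 <- min(model$exons[, 1L]); g1 <- max(model$exons[, 2L])
  plus <- model$strand == "+"
  cds <- cds_intervals(model)
  overlaps <- function(iv) any(iv[, 1L] < e & s < iv[, 2L])
  if (nrow(cds) && overlaps(cds)) return("exonic")
  u <- utr_segments(model)
  for (side in c("5", "3")) {
    us <- u[u$side == side, , drop = FALSE]
    if (nrow(us) && overlaps(cbind(us$start, us$end)))
      return(paste0("utr", side, "_exon"))
  }
  if (s < g1 && e > g0) {
    # intronic footprint; splice-adjacent if within 2 bp of a junction
    n_ex <- nrow(model$exons)
    for (i in seq_len(n_ex - 1L)) {
      i0 <- model$exons[i, 2L]; i1 <- model$exons[i + 1L, 1L]
      if (s < i1 && e > i0) {
        if (s < i0 + splice_bp || e > i1 - splice_bp) return("splicing")
        # UTR intron when the whole intron is outside the CDS span
        if (i1 <= model$cds_start)
          return(if (plus) "utr5_intron" else "utr3_intron")
        if (i0 >= model$cds_end)
          return(if (plus) "utr3_intron" else "utr5_intron")
        return("intronic")
      }
    }
    return("intronic")
  }
  if (e <= g0 && g0 - s <= window)
    return(if (plus) "upstream" else "downstream")
  if (s >= g1 && e - g1 <= window)
    return(if (plus) "downstream" else "upstream")
  "intergenic"
}

#' Locate an interval relative to a set of gene models
#'
#' Applies the positional precedence (CDS exon > UTR exon > splice-adjacent
#' > UTR intron > intronic > up/downstream within 1 kb > intergenic) over
#' all genes and returns the highest-precedence class.
#'
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @param models a \code{gene_model_set}.
#' @param window flank window for up/downstream (bp).
#' @return list with \code{class} and \code{gene} (NA when intergenic).
#' @export
locate_feature <- function(contig, start, end, models, window = 1000L) {
  precedence <- c("exonic", "utr5_exon", "utr3_exon", "splicing",
                  "utr5_intron", "utr3_intron", "intronic", "upstream",
                  "downstream", "intergenic")
  best <- "intergenic"; best_gene <- NA_character_
  for (m in models) {
    if (m$contig != contig) next
    cls <- .positional_class(start, end, m, window = window)
    if (match(cls, precedence) < match(best, precedence)) {
      best <- cls
      best_gene <- if (cls == "intergenic") NA_character_ else m$gene_name
    }
  }
  list(class = best, gene = best_gene)
}

#' Flag variants absent from a known-variant catalog
#'
#' @param calls variant-call data frame.
#' @param known_keys character vector of normalized keys (e.g. from
#'   [read_known_catalog()]).
#' @return logical vector, TRUE where the key is novel.
#' @export
mark_novel <- function(calls, known_keys) {
  !(variant_key(calls) %in% known_keys)
}

#' Annotate a variant table against gene models
#'
#' Produces one record per (variant, overlapping gene); variants touching
#' no gene (within the flank window) get a single intergenic record. SNVs
#' in the CDS are classified by codon translation; indels by CDS frame
#' parity; everything else positionally.
#'
#' @param calls variant-call data frame.
#' @param models a \code{gene_model_set}.
#' @param reference named character vector (or DNAStringSet).
#' @param known_keys optional known-variant keys for the novel flag.
#' @param window flank window (bp) for up/downstream assignment.
#' @return data frame: key, contig, pos, ref, alt, gene, class, novel,
#'   damaging.
#' @export
classify_variants <- function(calls, models, reference, known_keys = NULL,
                              window = 1000L) {
  refseq <- .as_ref_chr(reference)
  out <- list()
  keys <- variant_key(calls)
  novel <- if (is.null(known_keys)) rep(NA, nrow(calls)) else
    mark_novel(calls, known_keys)
  for (i in seq_len(nrow(calls))) {
    v <- calls[i, ]
    pos0 <- v$pos - 1L
    fe <- pos0 + max(nchar(v$ref), 1L)
    hit <- FALSE
    for (m in models) {
      if (m$contig != v$contig) next
      g0 <- min(m$exons[, 1L]) - window
      g1 <- max(m$exons[, 2L]) + window
      if (fe <= g0 || pos0 >= g1) next
      cls <- if (nchar(v$ref) == 1L && nchar(v$alt) == 1L)
        classify_snv(v, m, refseq) else classify_indel(v, m)
      out[[length(out) + 1L]] <- data.frame(
        key = keys[i], contig = v$contig, pos = v$pos, ref = v$ref,
        alt = v$alt, gene = m$gene_name, class = cls, novel = novel[i],
        damaging = if ("damaging" %in% names(v)) v$damaging else NA,
        stringsAsFactors = FALSE)
      hit <- TRUE
    }
    if (!hit)
      out[[length(out) + 1L]] <- data.frame(
        key = keys[i], contig = v$contig, pos = v$pos, ref = v$ref,
        alt = v$alt, gene = NA_character_, class = "intergenic",
        novel = novel[i],
        damaging = if ("damaging" %in% names(v)) v$damaging else NA,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(key = character(), contig = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene = character(), class = character(),
                      novel = logical(), damaging = logical(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Worst-consequence class per variant
#'
#' @param annotations output of [classify_variants()].
#' @return data frame with one row per key: the most severe class and the
#'   gene carrying it.
#' @export
worst_consequence <- function(annotations) {
  if (!nrow(annotations))
    return(annotations[0, c("key", "gene", "class")])
  sev <- class_severity(annotations$class)
  o <- order(annotations$key, sev)
  ann <- annotations[o, , drop = FALSE]
  ann[!duplicated(ann$key), c("key", "gene", "class")]
}

#' Tabulate functional-class counts the way the study tables report them
#'
#' Counts are per variant, using the worst-consequence class.
#'
#' @param annotations output of [classify_variants()].
#' @return named integer vector of class counts.
#' @export
class_counts <- function(annotations) {
  wc <- worst_consequence(annotations)
  tab <- table(factor(wc$class, levels = .SEVERITY))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
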