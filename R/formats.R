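# Readers and writers for the formats the pipeline touches. Readers go through
# established parsers (vcfR, rtracklayer, Rsamtools); writers emit plain text
# deterministically so that identical inputs give byte-identical files.

#' Read a VCF into a variant-call table
#'
#' Parses a VCF 4.2 file (single sample) into a data frame with one row per
#' (record, alt allele): multi-allelic records are split. Requires GT and DP
#' in FORMAT and MQ in INFO; optional INFO keys DMG=1 and KNOWN=1 populate
#' the damaging/known flags.
#'
#' @param path path to a VCF file.
#' @param sample_id sample identifier; defaults to the VCF sample column name.
#' @return data frame with columns contig, pos (1-based), ref, alt, depth,
#'   mq, gt, sample_id, damaging, known.
#' @export
read_vcf <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0L) return(.empty_calls(sample_id %||% "sample"))
  gtmat <- v@gt
  if (is.null(gtmat) || ncol(gtmat) < 2L)
    stop("VCF has no sample genotype column: ", path)
  if (is.null(sample_id)) sample_id <- colnames(gtmat)[2L]
  fmt <- strsplit(gtmat[, 1L], ":", fixed = TRUE)
  smp <- strsplit(gtmat[, 2L], ":", fixed = TRUE)
  get_field <- function(i, key) {
    j <- match(key, fmt[[i]])
    if (is.na(j)) stop("VCF record ", fix[i, "CHROM"], ":", fix[i, "POS"],
                       " lacks FORMAT field ", key)
    smp[[i]][j]
  }
  info <- fix[, "INFO"]
  mq <- suppressWarnings(as.numeric(sub(".*MQ=([0-9.eE+-]+).*", "\\1",
    ifelse(grepl("(^|;)MQ=", info), info, NA_character_))))
  if (anyNA(mq)) {
    bad <- which(is.na(mq))[1L]
    stop("VCF record ", fix[bad, "CHROM"], ":", fix[bad, "POS"],
         " lacks INFO field MQ")
  }
  dmg <- grepl("(^|;)DMG=1($|;)", info)
  kno <- grepl("(^|;)KNOWN=1($|;)", info)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- unname(strsplit(fix[[i, "ALT"]], ",", fixed = TRUE)[[1L]])
    rows[[i]] <- data.frame(
      contig = fix[[i, "CHROM"]],
      pos = as.integer(fix[[i, "POS"]]),
      ref = fix[[i, "REF"]],
      alt = alts,
      depth = as.integer(get_field(i, "DP")),
      mq = mq[i],
      gt = get_field(i, "GT"),
      sample_id = sample_id,
      damaging = dmg[i],
      known = kno[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  .validate_calls(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.empty_calls <- function(sample_id) {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), depth = integer(), mq = numeric(),
             gt = character(), sample_id = character(),
             damaging = logical(), known = logical(),
             stringsAsFactors = FALSE)
}

.validate_calls <- function(calls) {
  stopifnot(all(calls$depth >= 0), all(calls$pos >= 1))
  if (any(calls$ref == calls$alt))
    stop("ref allele equals alt allele at ",
         variant_key(calls)[which(calls$ref == calls$alt)[1L]])
  ok <- grepl("^[ACGT]+$", calls$ref) & grepl("^[ACGT]+$", calls$alt)
  if (!all(ok))
    stop("non-ACGT allele at ", variant_key(calls)[which(!ok)[1L]])
  invisible(calls)
}

#' Write a variant-call table as VCF 4.2
#'
#' @param calls data frame as returned by [read_vcf()].
#' @param path output path.
#' @export
write_vcf <- function(calls, path) {
  sid <- if (nrow(calls)) calls$sample_id[1L] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=DMG,Number=1,Type=Integer,Description=\"Predicted damaging flag\">",
    "##INFO=<ID=KNOWN,Number=1,Type=Integer,Description=\"Present in known-variant catalog\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sid, sep = "\t")
  )
  body <- character(0)
  if (nrow(calls)) {
    o <- order(calls$contig, calls$pos, calls$ref, calls$alt)
    calls <- calls[o, , drop = FALSE]
    info <- paste0("MQ=", format(calls$mq, trim = TRUE, scientific = FALSE),
                   ifelse(isTRUE_vec(calls$damaging), ";DMG=1", ""),
                   ifelse(isTRUE_vec(calls$known), ";KNOWN=1", ""))
    body <- paste(calls$contig, calls$pos, ".", calls$ref, calls$alt, ".",
                  "PASS", info, "GT:DP",
                  paste0(calls$gt, ":", calls$depth), sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Read gene models from a GFF3 subset
#'
#' Expects gene/mRNA/exon/CDS features (UTR features, if present, are
#' ignored and re-derived). One transcript per gene. Genes whose spliced CDS
#' length is not divisible by 3 are skipped with a warning; the number of
#' skipped genes is attached as attribute \code{n_skipped}.
#'
#' @param path GFF3 file.
#' @return list of gene models (class \code{gene_model_set}); each element
#'   has gene_name, contig, strand, exons (0-based half-open matrix),
#'   cds_start, cds_end.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    parent = vapply(as.list(gr$Parent %||% rep(list(character()), length(gr))),
                    function(p) if (length(p)) p[[1L]] else NA_character_,
                    character(1)),
    stringsAsFactors = FALSE
  )
  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  out <- list()
  n_skipped <- 0L
  for (i in seq_len(nrow(genes))) {
    gid <- genes$id[i]
    gname <- sub("^gene:", "", gid)
    tx <- mrnas[mrnas$parent == gid, , drop = FALSE]
    tid <- if (nrow(tx)) tx$id[1L] else gid
    ex <- df[df$type == "exon" & df$parent == tid, , drop = FALSE]
    cds <- df[df$type == "CDS" & df$parent == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    m <- gene_model(gene_name = gname, contig = genes$contig[i],
                    strand = genes$strand[i],
                    exons = cbind(ex$start, ex$end),
                    cds_start = if (nrow(cds)) min(cds$start) else NA_integer_,
                    cds_end = if (nrow(cds)) max(cds$end) else NA_integer_,
                    check_frame = FALSE)
    if (!is.na(m$cds_start) && spliced_cds_length(m) %% 3L != 0L) {
      warning("gene ", gname, ": spliced CDS length not divisible by 3; skipped")
      n_skipped <- n_skipped + 1L
      next
    }
    out[[length(out) + 1L]] <- m
  }
  class(out) <- "gene_model_set"
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Construct a gene model
#'
#' @param gene_name identifier.
#' @param contig contig name.
#' @param strand "+" or "-".
#' @param exons two-column matrix of 0-based half-open exon intervals.
#' @param cds_start,cds_end 0-based half-open genomic CDS bounds.
#' @param check_frame validate that the spliced CDS length is divisible by 3.
#' @return a \code{gene_model} list.
#' @export
gene_model <- function(gene_name, contig, strand, exons, cds_start, cds_end,
                       check_frame = TRUE) {
  exons <- matrix(as.integer(exons), ncol = 2L)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L && any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("gene ", gene_name, ": overlapping exons")
  if (!strand %in% c("+", "-")) stop("strand must be + or -")
  m <- list(gene_name = gene_name, contig = contig, strand = strand,
            exons = exons,
            cds_start = as.integer(cds_start), cds_end = as.integer(cds_end))
  class(m) <- "gene_model"
  if (check_frame && !is.na(m$cds_start) &&
      spliced_cds_length(m) %% 3L != 0L)
    stop("gene ", gene_name, ": spliced CDS length not divisible by 3")
  m
}

#' Spliced CDS length of a gene model (bp)
#' @param model a \code{gene_model}.
#' @export
spliced_cds_length <- function(model) {
  sum(vapply(seq_len(nrow(model$exons)), function(i) {
    max(0L, min(model$exons[i, 2L], model$cds_end) -
          max(model$exons[i, 1L], model$cds_start))
  }, integer(1)))
}

# exon pieces intersected with the CDS bounds, genomic order
cds_intervals <- function(model) {
  s <- pmax(model$exons[, 1L], model$cds_start)
  e <- pmin(model$exons[, 2L], model$cds_end)
  keep <- e > s
  cbind(s[keep], e[keep])
}

#' UTR segments of a gene model
#'
#' Exon parts outside the CDS, labelled 5'/3' strand-aware.
#'
#' @param model a \code{gene_model}.
#' @return data frame with columns start, end, side ("5" or "3").
#' @export
utr_segments <- function(model) {
  segs <- list()
  for (i in seq_len(nrow(model$exons))) {
    s <- model$exons[i, 1L]; e <- model$exons[i, 2L]
    left <- c(s, min(e, model$cds_start))
    right <- c(max(s, model$cds_end), e)
    if (left[2L] > left[1L])
      segs[[length(segs) + 1L]] <- c(left,
        if (model$strand == "+") 5L else 3L)
    if (right[2L] > right[1L])
      segs[[length(segs) + 1L]] <- c(right,
        if (model$strand == "+") 3L else 5L)
  }
  if (!length(segs))
    return(data.frame(start = integer(), end = integer(), side = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, segs)
  data.frame(start = m[, 1L], end = m[, 2L], side = as.character(m[, 3L]),
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3
#' @param models a \code{gene_model_set}.
#' @param path output path.
#' @export
write_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    g0 <- min(m$exons[, 1L]); g1 <- max(m$exons[, 2L])
    gid <- paste0("gene:", m$gene_name)
    tid <- paste0("tx:", m$gene_name)
    gff_row <- function(type, s, e, attrs) {
      paste(m$contig, "dynexome", type, s + 1L, e, ".", m$strand, ".",
            attrs, sep = "\t")
    }
    lines <- c(lines,
      gff_row("gene", g0, g1, paste0("ID=", gid, ";Name=", m$gene_name)),
      gff_row("mRNA", g0, g1, paste0("ID=", tid, ";Parent=", gid)))
    for (i in seq_len(nrow(m$exons)))
      lines <- c(lines, gff_row("exon", m$exons[i, 1L], m$exons[i, 2L],
                                paste0("ID=", tid, ".exon", i, ";Parent=", tid)))
    cds <- cds_intervals(m)
    for (i in seq_len(nrow(cds)))
      lines <- c(lines, gff_row("CDS", cds[i, 1L], cds[i, 2L],
                                paste0("ID=", tid, ".cds", i, ";Parent=", tid)))
    u <- utr_segments(m)
    for (i in seq_len(nrow(u))) {
      type <- if (u$side[i] == "5") "five_prime_UTR" else "three_prime_UTR"
      lines <- c(lines, gff_row(type, u$start[i], u$end[i],
                                paste0("ID=", tid, ".utr", i, ";Parent=", tid)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED4 coverage track
#'
#' @param path BED-like file: contig, start, end, depth (0-based half-open).
#' @return data frame with those columns; intervals must be sorted and
#'   non-overlapping within each contig.
#' @export
read_coverage <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("contig", "start", "end", "depth"))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$depth <- as.integer(df$depth)
  if (any(df$depth < 0) || any(df$end <= df$start))
    stop("malformed coverage interval in ", path)
  for (ctg in unique(df$contig)) {
    sub <- df[df$contig == ctg, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping coverage intervals on ", ctg, " in ", path)
  }
  df[order(df$contig, df$start), , drop = FALSE]
}

#' Write a BED4 coverage track
#' @param cov coverage data frame.
#' @param path output path.
#' @export
write_coverage <- function(cov, path) {
  cov <- cov[order(cov$contig, cov$start), , drop = FALSE]
  writeLines(paste(cov$contig, cov$start, cov$end, cov$depth, sep = "\t"),
             path)
  invisible(path)
}

#' Read / write BED3 target intervals
#' @param path BED3 file.
#' @return data frame contig, start, end (0-based half-open, sorted).
#' @export
read_targets <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("contig", "start", "end"))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) stop("malformed target interval in ", path)
  df[order(df$contig, df$start), , drop = FALSE]
}

#' @rdname read_targets
#' @param targets target data frame.
#' @export
write_targets <- function(targets, path) {
  targets <- targets[order(targets$contig, targets$start), , drop = FALSE]
  writeLines(paste(targets$contig, targets$start, targets$end, sep = "\t"),
             path)
  invisible(path)
}

#' Read a microsatellite locus catalog
#'
#' TSV with header columns contig, start0, end0, motif, ref_repeat_count
#' (0-based half-open tract bounds). Each row must satisfy
#' end0 - start0 == nchar(motif) * ref_repeat_count, and the motif must be
#' its own canonical rotation.
#'
#' @param path catalog TSV.
#' @return data frame contig, start, end, motif, ref_repeat_count, locus_id,
#'   and (if present in the file) location/gene columns.
#' @export
read_msat_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "start0", "end0", "motif", "ref_repeat_count")
  if (!all(need %in% names(df)))
    stop("catalog must have columns ", paste(need, collapse = ", "))
  out <- data.frame(contig = df$contig, start = as.integer(df$start0),
                    end = as.integer(df$end0), motif = df$motif,
                    ref_repeat_count = as.integer(df$ref_repeat_count),
                    stringsAsFactors = FALSE)
  bad <- out$end - out$start != nchar(out$motif) * out$ref_repeat_count
  if (any(bad))
    stop("catalog row ", which(bad)[1L],
         ": tract width does not equal motif length x repeat count")
  noncanon <- out$motif != canonical_motif(out$motif)
  if (any(noncanon))
    stop("catalog row ", which(noncanon)[1L], ": motif ",
         out$motif[which(noncanon)[1L]], " is not in canonical rotation")
  out$locus_id <- paste0(out$contig, ":", out$start, "-", out$end)
  for (extra in intersect(c("location", "gene"), names(df)))
    out[[extra]] <- df[[extra]]
  out
}

#' @rdname read_msat_catalog
#' @param catalog catalog data frame.
#' @export
write_msat_catalog <- function(catalog, path) {
  df <- data.frame(contig = catalog$contig, start0 = catalog$start,
                   end0 = catalog$end, motif = catalog$motif,
                   ref_repeat_count = catalog$ref_repeat_count,
                   stringsAsFactors = FALSE)
  for (extra in intersect(c("location", "gene"), names(catalog)))
    df[[extra]] <- catalog[[extra]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT-like term-to-gene-set annotation table
#'
#' Each line: term, description, then one gene per column.
#'
#' @param path GMT file.
#' @return named list of character gene vectors; descriptions in attribute
#'   \code{descriptions}.
#' @export
read_term_annotation <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3L
  if (any(bad)) stop("GMT line ", which(bad)[1L], " has fewer than 3 fields")
  terms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(terms)) stop("duplicate term in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- terms
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), terms)
  sets
}

#' Read a known-variant catalog (dbSNP stand-in)
#'
#' TSV with header columns contig, pos (1-based), ref, alt.
#'
#' @param path catalog TSV.
#' @return character vector of normalized variant keys.
#' @export
read_known_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    stop("known-variant catalog must have columns ",
         paste(need, collapse = ", "))
  variant_key(df)
}

#' Read aligned reads over microsatellite loci from SAM/BAM
#'
#' SAM files are converted with Rsamtools and scanned; only mapped reads are
#' returned.
#'
#' @param path SAM or BAM file.
#' @return data frame qname, contig, pos (1-based leftmost), cigar.
#' @export
read_sam_reads <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar", "flag")))[[1L]]
  keep <- !is.na(res$pos)
  data.frame(qname = res$qname[keep],
             contig = as.character(res$rname[keep]),
             pos = res$pos[keep],
             cigar = res$cigar[keep],
             stringsAsFactors = FALSE)
}

#' Write aligned reads as SAM
#'
#' @param reads data frame with qname, contig, pos (1-based), cigar, seq.
#' @param reference named character vector of contig sequences (for the
#'   header SQ lines).
#' @param path output path.
#' @export
write_sam_reads <- function(reads, reference, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(reference),
                  "\tLN:", nchar(reference)))
  reads <- reads[order(reads$contig, reads$pos, reads$qname), , drop = FALSE]
  body <- paste(reads$qname, 0L, reads$contig, reads$pos, 60L, reads$cigar,
                "*", 0L, 0L, reads$seq,
                vapply(nchar(reads$seq),
                       function(n) strrep("I", n), character(1)),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a named reference as FASTA
#' @param reference named character vector of contig sequences.
#' @param path output path.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), path, width = 70L)
  invisible(path)
}

#' Read a reference FASTA into a named character vector
#' @param path FASTA file.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}
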