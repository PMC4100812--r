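# hand-built single-exon gene: 10 bp pad | CDS ATG TAC CTG TAA | pad
.toy_ref <- function() {
  c(c1 = paste0("GGGGGGGGGG", "ATGTACCTGTAA", "CCCCCCCCCC"))
}
.toy_gene <- function() {
  gene_model("TOY", "c1", "+", cbind(0L, 32L), 10L, 22L)
}

# two-exon gene with an intron inside the CDS: exons [0,20)+[30,50),
# CDS [2,48), spliced length 36
.split_ref <- function() {
  set.seed(3)
  c(c2 = paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = ""))
}
.split_gene <- function() {
  gene_model("SPL", "c2", "+", rbind(c(0L, 20L), c(30L, 50L)), 2L, 48L)
}

test_that("codon-level SNV classes follow the genetic code", {
  ref <- .toy_ref(); g <- .toy_gene()
  # TAC -> TAA (3rd base C->A): stop gained
  v <- make_calls("c1", 16, "C", "A")
  expect_equal(classify_snv(v, g, ref), "stop_gain")
  # CTG -> CTA: both leucine
  v <- make_calls("c1", 19, "G", "A")
  expect_equal(classify_snv(v, g, ref), "synonymous")
  # TAA -> CAA: stop lost
  v <- make_calls("c1", 20, "T", "C")
  expect_equal(classify_snv(v, g, ref), "stop_loss")
  # TAC -> TCC: missense
  v <- make_calls("c1", 15, "A", "C")
  expect_equal(classify_snv(v, g, ref), "nonsynonymous")
  # reference mismatch is a data error
  v <- make_calls("c1", 16, "G", "A")
  expect_error(classify_snv(v, g, ref), "reference mismatch")
})

test_that("splice-adjacency is the first 2 bp of an intron", {
  ref <- .split_ref(); g <- .split_gene()
  snv_at <- function(pos1) {
    b <- substr(ref[["c2"]], pos1, pos1)
    make_calls("c2", pos1, b, setdiff(c("A", "C", "G", "T"), b)[1])
  }
  expect_equal(classify_snv(snv_at(21), g, ref), "splicing")  # 1 bp in
  expect_equal(classify_snv(snv_at(22), g, ref), "splicing")  # 2 bp in
  expect_equal(classify_snv(snv_at(23), g, ref), "intronic")  # 3 bp in
  expect_equal(classify_snv(snv_at(29), g, ref), "splicing")  # acceptor side
})

test_that("indel frame parity uses the CDS-overlapping length", {
  ref <- .split_ref(); g <- .split_gene()
  seqc <- ref[["c2"]]
  del <- function(pos0, len) {
    # anchored deletion of [pos0, pos0+len)
    make_calls("c2", pos0, substr(seqc, pos0, pos0 + len),
               substr(seqc, pos0, pos0))
  }
  # 3 bp wholly inside the CDS
  expect_equal(classify_indel(del(10, 3), g), "nonframeshift_indel")
  # 1 bp insertion inside the CDS
  ins <- make_calls("c2", 10, substr(seqc, 10, 10),
                    paste0(substr(seqc, 10, 10), "A"))
  expect_equal(classify_indel(ins, g), "frameshift_indel")
  # deletion spanning the exon/intron boundary: deletes bases 18..23
  # (0-based), of which 2 are CDS -> frameshift
  boundary <- del(18, 6)
  expect_equal(classify_indel(boundary, g), "frameshift_indel")
  # oracle: explicit spliced-CDS reconstruction after the deletion
  removed_cds <- length(intersect(18:23, 2:19))
  expect_equal(removed_cds %% 3 != 0,
               classify_indel(boundary, g) == "frameshift_indel")
  # deleting bases 17..19 (3 CDS bases) keeps the frame
  expect_equal(classify_indel(del(17, 3), g), "nonframeshift_indel")
})

test_that("indel class is invariant under left/right normalization", {
  # CDS containing an AAAA run: deletion of one A in either representation
  ref <- c(c3 = paste0("GGGGGGGGGG", "ATGAAAACTGTGTAA", "CCCCCCC"))
  g <- gene_model("RUN", "c3", "+", cbind(0L, 32L), 10L, 25L)
  left <- make_calls("c3", 13, "GA", "G")    # anchored at run start - 1
  right <- make_calls("c3", 16, "AA", "A")   # anchored inside the run
  expect_equal(classify_indel(left, g), classify_indel(right, g))
  norm <- normalize_variants(right, ref)
  expect_equal(variant_key(norm), variant_key(left))
})

test_that("random CDS SNVs match a translate-both-haplotypes oracle", {
  st <- small_study()
  ref <- st$assets$reference
  genes <- st$assets$genes
  set.seed(17)
  oracle_class <- function(v, m) {
    # independent path: mutate the contig, extract and translate the whole
    # spliced CDS on both haplotypes with Biostrings
    mut <- ref[[m$contig]]
    substr(mut, v$pos, v$pos) <- v$alt
    splice <- function(s) {
      cds <- rbind(
        pmax(m$exons[, 1], m$cds_start), pmin(m$exons[, 2], m$cds_end))
      keep <- cds[2, ] > cds[1, ]
      pieces <- mapply(function(a, b) substr(s, a + 1, b),
                       cds[1, keep], cds[2, keep])
      x <- Biostrings::DNAString(paste(pieces, collapse = ""))
      if (m$strand == "-") x <- Biostrings::reverseComplement(x)
      as.character(Biostrings::translate(x, no.init.codon = TRUE))
    }
    p_ref <- splice(ref[[m$contig]]); p_alt <- splice(mut)
    if (p_ref == p_alt) return("synonymous")
    i <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])[1]
    a <- substr(p_ref, i, i); b <- substr(p_alt, i, i)
    if (a != "*" && b == "*") return("stop_gain")
    if (a == "*" && b != "*") return("stop_loss")
    "nonsynonymous"
  }
  n_checked <- 0
  while (n_checked < 200) {
    m <- genes[[sample(length(genes), 1)]]
    cds <- cbind(pmax(m$exons[, 1], m$cds_start),
                 pmin(m$exons[, 2], m$cds_end))
    cds <- cds[cds[, 2] > cds[, 1], , drop = FALSE]
    row <- cds[sample(nrow(cds), 1), ]
    pos0 <- sample(row[1]:(row[2] - 1), 1)
    rb <- substr(ref[[m$contig]], pos0 + 1, pos0 + 1)
    ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    v <- make_calls(m$contig, pos0 + 1, rb, ab)
    expect_equal(classify_snv(v, m, ref), oracle_class(v, m),
                 label = paste("SNV at", m$contig, pos0 + 1, "in",
                               m$gene_name))
    n_checked <- n_checked + 1
  }
})

test_that("mirrored gene and reference give identical classes", {
  ref <- .toy_ref(); g <- .toy_gene()
  L <- nchar(ref[["c1"]])
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(ref[["c1"]], "")[[1]]]), collapse = "")
  ref_rc <- c(c1 = rc)
  g_rc <- gene_model("TOY", "c1", "-",
                     cbind(L - g$exons[, 2], L - g$exons[, 1]),
                     L - g$cds_end, L - g$cds_start)
  for (pos1 in c(15, 16, 19, 20)) {
    rb <- substr(ref[["c1"]], pos1, pos1)
    for (ab in setdiff(c("A", "C", "G", "T"), rb)) {
      v <- make_calls("c1", pos1, rb, ab)
      v_rc <- make_calls("c1", L - pos1 + 1, unname(comp[rb]),
                         unname(comp[ab]))
      expect_equal(classify_snv(v, g, ref),
                   classify_snv(v_rc, g_rc, ref_rc))
    }
  }
})

test_that("positional classes of simulated loci match their planted labels", {
  st <- small_study()
  cat <- st$assets$msat_catalog
  for (i in seq_len(nrow(cat))) {
    loc <- locate_feature(cat$contig[i], cat$start[i], cat$end[i],
                          st$assets$genes)
    expect_equal(loc$class, cat$location[i],
                 label = paste("locus", cat$locus_id[i]))
    if (cat$location[i] != "intergenic")
      expect_equal(loc$gene, cat$gene[i])
  }
})

test_that("novelty is catalog-membership by normalized key", {
  calls <- make_calls("c1", c(10, 20), "A", "T")
  keys <- variant_key(calls)
  expect_equal(mark_novel(calls, keys[1]), c(FALSE, TRUE))
  expect_equal(mark_novel(calls, character(0)), c(TRUE, TRUE))
})

test_that("worst consequence follows the severity order", {
  ann <- data.frame(
    key = c("k1", "k1", "k2"), contig = "c", pos = 1L, ref = "A",
    alt = "T", gene = c("G1", "G2", "G1"),
    class = c("synonymous", "nonsynonymous", "stop_gain"),
    novel = NA, damaging = NA, stringsAsFactors = FALSE)
  wc <- worst_consequence(ann)
  expect_equal(wc$class[wc$key == "k1"], "nonsynonymous")
  expect_equal(wc$gene[wc$key == "k1"], "G2")
  expect_equal(wc$class[wc$key == "k2"], "stop_gain")
})
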