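test_that("VCF fields map directly and multi-allelic records split", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t101\t.\tA\tT\t.\tPASS\tMQ=60\tGT:DP\t0/1:20",
    "chr1\t300\t.\tA\tT,C\t.\tPASS\tMQ=55\tGT:DP\t1/2:30"
  ), path)
  calls <- read_vcf(path)
  expect_equal(nrow(calls), 3)
  expect_equal(calls$pos[1], 101)
  expect_equal(calls$depth[1], 20)
  expect_equal(calls$mq[1], 60)
  split_rows <- calls[calls$pos == 300, ]
  expect_setequal(split_rows$alt, c("T", "C"))
  expect_equal(unique(split_rows$pos), 300)
})

test_that("VCF reader rejects records missing MQ", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t101\t.\tA\tT\t.\tPASS\t.\tGT:DP\t0/1:20"
  ), path)
  expect_error(read_vcf(path), "MQ")
})

test_that("simulated calls round-trip through write_vcf/read_vcf", {
  st <- small_study()
  calls <- do.call(rbind, lapply(st$samples[1:2], `[[`, "calls"))
  calls$sample_id <- "merged"
  path <- tempfile(fileext = ".vcf")
  write_vcf(calls, path)
  back <- read_vcf(path, sample_id = "merged")
  o <- order(calls$contig, calls$pos, calls$ref, calls$alt)
  calls <- calls[o, ]
  rownames(calls) <- rownames(back) <- NULL
  expect_equal(back, calls)
})

test_that("gene models round-trip through GFF3 and UTRs are re-derived", {
  st <- small_study()
  path <- tempfile(fileext = ".gff3")
  write_gene_models(st$assets$genes, path)
  back <- read_gene_models(path)
  expect_equal(length(back), length(st$assets$genes))
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$gene_name, st$assets$genes[[i]]$gene_name)
    expect_equal(back[[i]]$exons, st$assets$genes[[i]]$exons,
                 ignore_attr = TRUE)
    expect_equal(back[[i]]$cds_start, st$assets$genes[[i]]$cds_start)
    expect_equal(back[[i]]$cds_end, st$assets$genes[[i]]$cds_end)
  }
})

test_that("UTR derivation follows the exon-minus-CDS set difference", {
  # single-exon gene whose CDS is the whole exon: no UTR
  m1 <- gene_model("g1", "c", "+", cbind(100L, 400L), 100L, 400L)
  expect_equal(nrow(utr_segments(m1)), 0)
  # CDS starting mid-exon-1 on + strand: one 5' UTR segment
  m2 <- gene_model("g2", "c", "+", rbind(c(100L, 200L), c(300L, 400L)),
                   150L, 400L)
  u <- utr_segments(m2)
  expect_equal(nrow(u), 1)
  expect_equal(u$side, "5")
  expect_equal(c(u$start, u$end), c(100, 150))
})

test_that("frame-violating CDS models are skipped with a warning", {
  path <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tx\tgene\t101\t200\t.\t+\t.\tID=gene:BAD",
    "c1\tx\tmRNA\t101\t200\t.\t+\t.\tID=tx:BAD;Parent=gene:BAD",
    "c1\tx\texon\t101\t200\t.\t+\t.\tID=e1;Parent=tx:BAD",
    "c1\tx\tCDS\t101\t200\t.\t+\t.\tID=c1;Parent=tx:BAD"
  ), path)
  expect_warning(models <- read_gene_models(path), "divisible by 3")
  expect_length(models, 0)
  expect_equal(attr(models, "n_skipped"), 1)
})

test_that("coverage reader parses BED4 and rejects overlaps", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\t12", "chr1\t100\t150\t3"), path)
  cov <- read_coverage(path)
  expect_equal(cov$start, c(0, 100))
  expect_equal(cov$depth, c(12, 3))
  writeLines(c("chr1\t0\t100\t12", "chr1\t50\t150\t3"), path)
  expect_error(read_coverage(path), "overlapping")
})

test_that("microsatellite catalog validation enforces tract arithmetic", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tstart0\tend0\tmotif\tref_repeat_count",
               "chr1\t100\t115\tAGG\t5"), path)
  cat <- read_msat_catalog(path)
  expect_equal(cat$end - cat$start, 15)
  writeLines(c("contig\tstart0\tend0\tmotif\tref_repeat_count",
               "chr1\t100\t114\tAGG\t5"), path)
  expect_error(read_msat_catalog(path), "tract width")
  writeLines(c("contig\tstart0\tend0\tmotif\tref_repeat_count",
               "chr1\t100\t115\tCAG\t5"), path)
  expect_error(read_msat_catalog(path), "canonical")
})

test_that("GMT-like term annotation parses terms and gene sets", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("DiseaseX\tdesc\tG1\tG2\tG3", "DiseaseY\tdesc\tG2"), path)
  sets <- read_term_annotation(path)
  expect_length(sets$DiseaseX, 3)
  expect_equal(sets$DiseaseY, "G2")
  writeLines("Broken\tdesc", path)
  expect_error(read_term_annotation(path), "fewer than 3")
})

test_that("SAM reads round-trip through Rsamtools", {
  st <- small_study()
  s <- st$samples[[1]]
  path <- tempfile(fileext = ".sam")
  write_sam_reads(s$reads, st$assets$reference, path)
  back <- read_sam_reads(path)
  expect_equal(nrow(back), nrow(s$reads))
  orig <- s$reads[order(s$reads$qname), c("qname", "contig", "pos", "cigar")]
  back <- back[order(back$qname), c("qname", "contig", "pos", "cigar")]
  rownames(orig) <- rownames(back) <- NULL
  expect_equal(back, orig)
})

test_that("indel normalization left-aligns and trims minimal alleles", {
  ref <- c(c1 = "GGATATATCC")
  # deletion of "AT" inside the AT run, given right-shifted: pos 6 "TAT"->"T"
  calls <- make_calls("c1", 6, "TAT", "T")
  norm <- normalize_variants(calls, ref)
  expect_equal(norm$pos, 2)
  expect_equal(norm$ref, "GAT")
  expect_equal(norm$alt, "G")
  # shared suffix is trimmed: "AC"->"TC" is really "A"->"T"
  norm2 <- normalize_variants(make_calls("c1", 3, "AC", "TC"), ref)
  expect_equal(c(norm2$ref, norm2$alt), c("A", "T"))
})
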