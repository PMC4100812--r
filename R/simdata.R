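# Synthetic mini-exome study generator. Emulates the serial-exome study
# design: several individuals sampled at 2-3 ages, a shared baseline variant
# set per individual, Poisson-implanted acquired variants at a per-bp-per-year
# rate, occasional loss of previously present variants, depth-variable
# coverage so some loci fail the 5-read callability rule, and microsatellite
# loci with implanted repeat-length changes plus stutter-noisy spanning reads.

#' Configuration for the synthetic serial-exome study
#'
#' Defaults encode the study design the pipeline targets: three individuals
#' sampled at ages 17/30, 29/45 and 42/51/57, 152x mean coverage, a
#' nonsynonymous-scale acquisition rate of 2e-6 per bp per year (within the
#' observed per-individual range of ~1e-6 to ~8e-6) and a microsatellite
#' change rate of 2.5e-4 per locus per year. Genome sizes are desk-scale.
#'
#' @param n_contigs number of contigs.
#' @param contig_length bp per contig.
#' @param n_genes number of genes (distributed across contigs).
#' @param exons_per_gene exons per gene (>= 1; >= 4 gives UTR introns).
#' @param n_microsat_loci microsatellite loci, cycled over location classes.
#' @param motif_alphabet repeat units (1-4 bp, canonical rotation).
#' @param baseline_variant_rate baseline variants per target bp.
#' @param acquired_rate acquired variants per target bp per year.
#' @param microsat_change_rate genotype changes per locus per year.
#' @param lost_rate probability per year that a present variant is lost.
#' @param ages named list, ages (years) per individual, strictly increasing.
#' @param mean_depth mean sequencing depth.
#' @param depth_dispersion negative-binomial size parameter for per-block
#'   depth; 0 means uniform depth equal to \code{mean_depth}.
#' @param stutter_prob probability a spanning read mis-reports the repeat
#'   count by one unit (must be < 0.5).
#' @param read_length spanning-read length (bp).
#' @param damaging_frac fraction of variants flagged damaging.
#' @param known_frac fraction of variants present in the known catalog.
#' @param low_mq_frac fraction of variant loci with low mapping quality.
#' @param seed integer RNG seed; all outputs are reproducible from it.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_contigs = 2L, contig_length = 100000L,
                       n_genes = 30L, exons_per_gene = 4L,
                       n_microsat_loci = 36L,
                       motif_alphabet = c("A", "AC", "AG", "AGC", "AGG",
                                          "CCT", "CCTT"),
                       baseline_variant_rate = 1e-3,
                       acquired_rate = 2e-6,
                       microsat_change_rate = 2.5e-4,
                       lost_rate = 0.002,
                       ages = list(individual1 = c(17, 30),
                                   individual2 = c(29, 45),
                                   individual3 = c(42, 51, 57)),
                       mean_depth = 152, depth_dispersion = 8,
                       stutter_prob = 0.02, read_length = 150L,
                       damaging_frac = 0.1, known_frac = 0.5,
                       low_mq_frac = 0.03, seed = 42L) {
  cfg <- list(n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              n_microsat_loci = as.integer(n_microsat_loci),
              motif_alphabet = motif_alphabet,
              baseline_variant_rate = baseline_variant_rate,
              acquired_rate = acquired_rate,
              microsat_change_rate = microsat_change_rate,
              lost_rate = lost_rate, ages = ages,
              mean_depth = mean_depth, depth_dispersion = depth_dispersion,
              stutter_prob = stutter_prob,
              read_length = as.integer(read_length),
              damaging_frac = damaging_frac, known_frac = known_frac,
              low_mq_frac = low_mq_frac, seed = as.integer(seed))
  rates <- c(cfg$baseline_variant_rate, cfg$acquired_rate,
             cfg$microsat_change_rate, cfg$lost_rate)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (cfg$stutter_prob < 0 || cfg$stutter_prob >= 0.5)
    stop("stutter_prob must be in [0, 0.5)")
  if (!length(cfg$ages) || is.null(names(cfg$ages)))
    stop("ages must be a named list, one element per individual")
  for (a in cfg$ages)
    if (length(a) < 1L || any(diff(a) <= 0))
      stop("ages must be strictly increasing per individual")
  bad <- cfg$motif_alphabet != canonical_motif(cfg$motif_alphabet)
  if (any(bad))
    stop("motif ", cfg$motif_alphabet[which(bad)[1L]],
         " is not in canonical rotation")
  if (any(nchar(cfg$motif_alphabet) > 4L | nchar(cfg$motif_alphabet) < 1L))
    stop("motifs must be 1-4 bp")
  class(cfg) <- "sim_config"
  cfg
}

# fixed internal geometry
.SIM_EXON_LEN <- 150L
.SIM_INTRON_LEN <- 300L
.SIM_GENE_GAP <- 2500L
.SIM_OFFSET0 <- 2000L
.SIM_UTR_PAD <- 30L      # CDS starts/ends this far inside its terminal exons
.SIM_TARGET_PAD <- 10L   # exon padding included in target intervals
.SIM_COV_BLOCK <- 50L    # coverage block size (bp)

.MSAT_CLASSES <- c("exonic", "intronic", "utr3_exon", "utr5_exon",
                   "utr3_intron", "utr5_intron", "downstream", "upstream",
                   "intergenic")

#' Build the synthetic reference, gene models, targets and locus catalog
#'
#' Generates random contig sequences, lays out genes (non-overlapping exons,
#' frame-consistent CDS, explicit UTR exons and UTR introns), embeds perfect
#' microsatellite tracts at positions realizing each location class, and
#' derives the target intervals (padded exons plus microsatellite windows).
#'
#' @param config a [sim_config()].
#' @return a \code{sim_assets} list: reference (named character), genes
#'   (\code{gene_model_set}), targets, msat_catalog (with truth location and
#'   gene columns), config.
#' @export
build_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ref <- lapply(seq_len(config$n_contigs), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$contig_length,
                 replace = TRUE), collapse = "")
  })
  names(ref) <- paste0("ctg", seq_len(config$n_contigs))
  ref <- unlist(ref)

  # gene layout
  n_ex <- config$exons_per_gene
  span <- n_ex * .SIM_EXON_LEN + max(0L, n_ex - 1L) * .SIM_INTRON_LEN
  pitch <- span + .SIM_GENE_GAP
  per_contig <- ceiling(config$n_genes / config$n_contigs)
  if (config$n_genes > 0L &&
      .SIM_OFFSET0 + per_contig * pitch > config$contig_length - 2000L)
    stop("feature footprint exceeds contig capacity: need ",
         .SIM_OFFSET0 + per_contig * pitch, " bp, have ",
         config$contig_length - 2000L)

  genes <- list()
  for (g in seq_len(config$n_genes)) {
    ctg_i <- ((g - 1L) %% config$n_contigs) + 1L
    slot <- (g - 1L) %/% config$n_contigs
    gstart <- .SIM_OFFSET0 + slot * pitch
    exon_starts <- gstart + (seq_len(n_ex) - 1L) *
      (.SIM_EXON_LEN + .SIM_INTRON_LEN)
    exons <- cbind(exon_starts, exon_starts + .SIM_EXON_LEN)
    strand <- if (g %% 2L == 1L) "+" else "-"
    first_cds_ex <- min(2L, n_ex)
    last_cds_ex <- max(n_ex - 1L, first_cds_ex)
    cds_start <- exons[first_cds_ex, 1L] + .SIM_UTR_PAD
    cds_end <- exons[last_cds_ex, 2L] - .SIM_UTR_PAD
    m <- gene_model(sprintf("GENE%03d", g), names(ref)[ctg_i], strand,
                    exons, cds_start, cds_end, check_frame = FALSE)
    excess <- spliced_cds_length(m) %% 3L
    m$cds_end <- m$cds_end - excess
    genes[[g]] <- m
  }
  class(genes) <- "gene_model_set"

  # microsatellite placement
  placements <- .place_msat_loci(config, genes, ref)
  catalog <- placements$catalog
  for (i in seq_len(nrow(catalog))) {
    tract <- strrep(catalog$motif[i], catalog$ref_repeat_count[i])
    ctg <- catalog$contig[i]
    s <- catalog$start[i]; e <- catalog$end[i]
    seq <- ref[[ctg]]
    substr(seq, s + 1L, e) <- tract
    # force the tract to be maximal: flanking bases differ from the motif edge
    first_ch <- substr(catalog$motif[i], 1L, 1L)
    last_ch <- substr(catalog$motif[i], nchar(catalog$motif[i]),
                      nchar(catalog$motif[i]))
    if (s >= 1L)
      substr(seq, s, s) <- setdiff(c("A", "C", "G", "T"), last_ch)[1L]
    if (e < nchar(seq))
      substr(seq, e + 1L, e + 1L) <- setdiff(c("A", "C", "G", "T"),
                                             first_ch)[1L]
    ref[[ctg]] <- seq
  }

  # targets: padded exons plus microsatellite windows
  tgt <- list()
  for (m in genes) {
    for (i in seq_len(nrow(m$exons)))
      tgt[[length(tgt) + 1L]] <- data.frame(
        contig = m$contig,
        start = m$exons[i, 1L] - .SIM_TARGET_PAD,
        end = m$exons[i, 2L] + .SIM_TARGET_PAD,
        stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(catalog)))
    tgt[[length(tgt) + 1L]] <- data.frame(
      contig = catalog$contig[i], start = catalog$start[i] - 20L,
      end = catalog$end[i] + 20L, stringsAsFactors = FALSE)
  targets <- if (length(tgt)) {
    gr <- GenomicRanges::reduce(.intervals_to_granges(do.call(rbind, tgt)))
    .granges_to_intervals(gr)
  } else {
    data.frame(contig = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)
  }

  out <- list(reference = ref, genes = genes, targets = targets,
              msat_catalog = catalog, config = config)
  class(out) <- "sim_assets"
  out
}

.place_msat_loci <- function(config, genes, ref) {
  n <- config$n_microsat_loci
  cat_rows <- list()
  used <- character(0)
  triplets <- config$motif_alphabet[nchar(config$motif_alphabet) == 3L]
  if (!length(triplets)) triplets <- config$motif_alphabet
  inter_cursor <- stats::setNames(rep(NA_integer_, length(ref)), names(ref))
  gene_tail <- stats::setNames(rep(0L, length(ref)), names(ref))
  for (m in genes)
    gene_tail[m$contig] <- max(gene_tail[m$contig], max(m$exons[, 2L]))

  for (i in seq_len(n)) {
    cls <- .MSAT_CLASSES[((i - 1L) %% length(.MSAT_CLASSES)) + 1L]
    motif <- if (cls == "exonic") {
      triplets[((i - 1L) %/% length(.MSAT_CLASSES)) %% length(triplets) + 1L]
    } else {
      config$motif_alphabet[((i - 1L) %% length(config$motif_alphabet)) + 1L]
    }
    count <- sample(6:10, 1L)
    if (nchar(motif) == 1L) count <- count + 6L
    tract_len <- nchar(motif) * count

    if (cls == "intergenic") {
      ctg <- names(ref)[((i - 1L) %% length(ref)) + 1L]
      cur <- inter_cursor[ctg]
      if (is.na(cur)) cur <- gene_tail[ctg] + 1500L
      s <- cur
      inter_cursor[ctg] <- cur + tract_len + 300L
      if (s + tract_len > nchar(ref[[ctg]]) - 100L)
        stop("feature footprint exceeds contig capacity (microsatellites)")
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        contig = ctg, start = s, end = s + tract_len, motif = motif,
        ref_repeat_count = count, location = cls, gene = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    if (!length(genes)) stop("gene-relative microsatellite class ", cls,
                             " requires n_genes > 0")
    placed <- FALSE
    for (try_g in seq_along(genes)) {
      g <- ((i - 1L + try_g - 1L) %% length(genes)) + 1L
      if (paste(g, cls) %in% used) next
      mgene <- genes[[g]]
      s <- .msat_anchor(mgene, cls, tract_len)
      if (is.na(s)) next
      used <- c(used, paste(g, cls))
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        contig = mgene$contig, start = s, end = s + tract_len,
        motif = motif, ref_repeat_count = count, location = cls,
        gene = mgene$gene_name, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) stop("unable to place microsatellite locus ", i,
                      " of class ", cls, "; increase n_genes")
  }
  catalog <- if (length(cat_rows)) do.call(rbind, cat_rows) else
    data.frame(contig = character(), start = integer(), end = integer(),
               motif = character(), ref_repeat_count = integer(),
               location = character(), gene = character(),
               stringsAsFactors = FALSE)
  catalog$locus_id <- if (nrow(catalog))
    paste0(catalog$contig, ":", catalog$start, "-", catalog$end) else
      character(0)
  list(catalog = catalog)
}

# genomic start for a tract of the given class within/near a gene, or NA
.msat_anchor <- function(m, cls, tract_len) {
  n_ex <- nrow(m$exons)
  plus <- m$strand == "+"
  fit <- function(s, e) if (e - s >= tract_len + 4L) s + 2L else NA_integer_
  switch(cls,
    exonic = {
      cds <- cds_intervals(m)
      # a middle coding exon, fully inside the CDS where possible
      j <- which.max(cds[, 2L] - cds[, 1L])
      s <- fit(cds[j, 1L] + 6L, cds[j, 2L] - 6L)
      s
    },
    intronic = {
      if (n_ex < 2L) return(NA_integer_)
      # an intron interior to the CDS (exists when exons_per_gene >= 4)
      j <- max(2L, min(n_ex - 2L, n_ex - 1L))
      s0 <- m$exons[j, 2L]; e0 <- m$exons[j + 1L, 1L]
      fit(s0 + 20L, e0 - 20L)
    },
    utr5_exon = {
      ex <- if (plus) m$exons[1L, ] else m$exons[n_ex, ]
      u <- utr_segments(m); u <- u[u$side == "5", , drop = FALSE]
      if (!nrow(u)) return(NA_integer_)
      j <- which.max(u$end - u$start)
      fit(u$start[j], u$end[j])
    },
    utr3_exon = {
      u <- utr_segments(m); u <- u[u$side == "3", , drop = FALSE]
      if (!nrow(u)) return(NA_integer_)
      j <- which.max(u$end - u$start)
      fit(u$start[j], u$end[j])
    },
    utr5_intron = {
      if (n_ex < 2L) return(NA_integer_)
      j <- if (plus) 1L else n_ex - 1L
      s0 <- m$exons[j, 2L]; e0 <- m$exons[j + 1L, 1L]
      # intron must lie wholly on the 5' side of the CDS
      if (plus && e0 > m$cds_start) return(NA_integer_)
      if (!plus && s0 < m$cds_end) return(NA_integer_)
      fit(s0 + 20L, e0 - 20L)
    },
    utr3_intron = {
      if (n_ex < 2L) return(NA_integer_)
      j <- if (plus) n_ex - 1L else 1L
      s0 <- m$exons[j, 2L]; e0 <- m$exons[j + 1L, 1L]
      if (plus && s0 < m$cds_end) return(NA_integer_)
      if (!plus && e0 > m$cds_start) return(NA_integer_)
      fit(s0 + 20L, e0 - 20L)
    },
    upstream = {
      if (plus) min(m$exons[, 1L]) - 200L - tract_len
      else max(m$exons[, 2L]) + 200L
    },
    downstream = {
      if (plus) max(m$exons[, 2L]) + 200L
      else min(m$exons[, 1L]) - 200L - tract_len
    },
    stop("unknown class ", cls))
}

# map linear target-space indices (1..target_bp) to (contig, pos0)
.target_index <- function(targets) {
  w <- targets$end - targets$start
  list(targets = targets, cum = cumsum(w), total = sum(w))
}

.index_to_pos <- function(idx, ti) {
  row <- findInterval(idx - 1L, c(0L, ti$cum), rightmost.closed = FALSE)
  off <- idx - c(0L, ti$cum)[row] - 1L
  data.frame(contig = ti$targets$contig[row],
             pos0 = ti$targets$start[row] + off,
             stringsAsFactors = FALSE)
}

#' Total target width (bp) of a simulated study
#' @param assets a \code{sim_assets} object.
#' @export
target_width <- function(assets) {
  sum(assets$targets$end - assets$targets$start)
}

#' Simulate serial time points: variants, coverage, spanning reads, truth
#'
#' For each individual, draws a shared baseline variant set, implants
#' acquired variants per time interval with Poisson counts at
#' \code{acquired_rate * target_bp * dt}, removes present variants at
#' \code{lost_rate} per year, draws block-wise negative-binomial coverage,
#' and emits stutter-noisy spanning reads over every microsatellite locus.
#' Every implant is recorded in the truth tables.
#'
#' @param assets output of [build_reference()].
#' @return a \code{sim_study} list: assets, samples (per-sample calls,
#'   coverage, reads), truth (variants, msat_genotypes, msat_changes),
#'   known_keys.
#' @export
simulate_timepoints <- function(assets) {
  stopifnot(inherits(assets, "sim_assets"))
  cfg <- assets$config
  set.seed(cfg$seed + 1000L)
  ti <- .target_index(assets$targets)
  refseq <- assets$reference

  truth_rows <- list()
  for (ind in names(cfg$ages)) {
    ages <- cfg$ages[[ind]]
    n_base <- stats::rpois(1L, cfg$baseline_variant_rate * ti$total)
    vt <- .draw_variants(n_base, ti, refseq, cfg, exclude = character(0))
    vt$individual <- if (nrow(vt)) ind else character(0)
    vt$origin <- if (nrow(vt)) "baseline" else character(0)
    vt$acquired_after <- rep(NA_real_, nrow(vt))
    vt$acquired_by <- rep(NA_real_, nrow(vt))
    existing <- variant_key(vt)
    acq <- list()
    for (j in seq_along(ages)[-1L]) {
      dt <- ages[j] - ages[j - 1L]
      n_acq <- stats::rpois(1L, cfg$acquired_rate * ti$total * dt)
      av <- .draw_variants(n_acq, ti, refseq, cfg, exclude = existing)
      if (nrow(av)) {
        av$individual <- ind
        av$origin <- "acquired"
        av$acquired_after <- ages[j - 1L]
        av$acquired_by <- ages[j]
        existing <- c(existing, variant_key(av))
        acq[[length(acq) + 1L]] <- av
      }
    }
    vt <- rbind(vt, if (length(acq)) do.call(rbind, acq))
    # losses: each present variant can be lost in any later interval
    vt$lost_after <- rep(NA_real_, nrow(vt))
    vt$lost_by <- rep(NA_real_, nrow(vt))
    for (j in seq_along(ages)[-1L]) {
      dt <- ages[j] - ages[j - 1L]
      p_lost <- 1 - exp(-cfg$lost_rate * dt)
      present <- is.na(vt$lost_by) &
        (vt$origin == "baseline" |
           (!is.na(vt$acquired_by) & vt$acquired_by <= ages[j - 1L]))
      hit <- present & stats::runif(nrow(vt)) < p_lost
      vt$lost_after[hit] <- ages[j - 1L]
      vt$lost_by[hit] <- ages[j]
    }
    truth_rows[[ind]] <- vt
  }
  truth_variants <- do.call(rbind, truth_rows)
  rownames(truth_variants) <- NULL

  known_keys <- variant_key(truth_variants)[isTRUE_vec(truth_variants$known)]
  known_keys <- unique(known_keys)

  # microsatellite truth genotypes and changes
  cat <- assets$msat_catalog
  geno_rows <- list(); change_rows <- list()
  for (ind in if (nrow(cat)) names(cfg$ages) else character(0)) {
    ages <- cfg$ages[[ind]]
    a1 <- cat$ref_repeat_count
    a2 <- cat$ref_repeat_count
    het <- stats::runif(nrow(cat)) < 0.2
    a2[het] <- pmax(2L, a2[het] + sample(c(-1L, 1L), sum(het),
                                         replace = TRUE))
    cur <- cbind(a1, a2)
    for (j in seq_along(ages)) {
      if (j > 1L) {
        dt <- ages[j] - ages[j - 1L]
        p_change <- pmin(1, cfg$microsat_change_rate * dt)
        chg <- stats::runif(nrow(cat)) < p_change
        for (k in which(chg)) {
          ai <- sample(1:2, 1L)
          delta <- sample(c(-1L, 1L), 1L)
          newv <- max(2L, cur[k, ai] + delta)
          if (newv == cur[k, ai]) { newv <- cur[k, ai] + 1L; delta <- 1L }
          cur[k, ai] <- newv
          change_rows[[length(change_rows) + 1L]] <- data.frame(
            individual = ind, locus_id = cat$locus_id[k],
            interval_start = ages[j - 1L], interval_end = ages[j],
            allele_index = ai, delta = delta, stringsAsFactors = FALSE)
        }
      }
      geno_rows[[length(geno_rows) + 1L]] <- data.frame(
        individual = ind, age = ages[j], locus_id = cat$locus_id,
        a1 = pmin(cur[, 1L], cur[, 2L]), a2 = pmax(cur[, 1L], cur[, 2L]),
        stringsAsFactors = FALSE)
    }
  }
  truth_msat_genotypes <- if (length(geno_rows)) {
    do.call(rbind, geno_rows)
  } else {
    data.frame(individual = character(), age = numeric(),
               locus_id = character(), a1 = integer(), a2 = integer(),
               stringsAsFactors = FALSE)
  }
  truth_msat_changes <- if (length(change_rows)) {
    do.call(rbind, change_rows)
  } else {
    data.frame(individual = character(), locus_id = character(),
               interval_start = numeric(), interval_end = numeric(),
               allele_index = integer(), delta = integer(),
               stringsAsFactors = FALSE)
  }

  # per-sample coverage, calls, spanning reads
  samples <- list()
  for (ind in names(cfg$ages)) {
    for (age in cfg$ages[[ind]]) {
      sid <- paste0(ind, "_y", age)
      cov <- .draw_coverage(assets, cfg)
      vt <- truth_variants[truth_variants$individual == ind, , drop = FALSE]
      present <- (vt$origin == "baseline" |
                    (!is.na(vt$acquired_by) & vt$acquired_by <= age)) &
        (is.na(vt$lost_by) | vt$lost_by > age)
      vp <- vt[present, , drop = FALSE]
      dp <- .depth_at(cov, vp$contig, vp$pos - 1L)
      keep <- dp >= 1L
      calls <- if (any(keep)) {
        data.frame(contig = vp$contig[keep], pos = vp$pos[keep],
                   ref = vp$ref[keep], alt = vp$alt[keep],
                   depth = dp[keep], mq = vp$mq[keep],
                   gt = vp$gt[keep], sample_id = sid,
                   damaging = vp$damaging[keep],
                   known = vp$known[keep], stringsAsFactors = FALSE)
      } else {
        .empty_calls(sid)
      }
      gt_now <- truth_msat_genotypes[
        truth_msat_genotypes$individual == ind &
          truth_msat_genotypes$age == age, , drop = FALSE]
      reads <- .draw_spanning_reads(assets, cfg, cov, gt_now, sid)
      samples[[sid]] <- list(sample_id = sid, individual = ind, age = age,
                             calls = calls, coverage = cov, reads = reads)
    }
  }

  out <- list(assets = assets, samples = samples,
              truth = list(variants = truth_variants,
                           msat_genotypes = truth_msat_genotypes,
                           msat_changes = truth_msat_changes),
              known_keys = known_keys)
  class(out) <- "sim_study"
  out
}

# draw n distinct variants over the target space (90% SNV, 10% indel)
.draw_variants <- function(n, ti, refseq, cfg, exclude) {
  if (n == 0L)
    return(cbind(.empty_calls("truth")[0, 1:4],
                 data.frame(mq = numeric(0), gt = character(0),
                            damaging = logical(0), known = logical(0))))
  rows <- list()
  tries <- 0L
  while (length(rows) < n && tries < 50L * n + 100L) {
    tries <- tries + 1L
    idx <- sample.int(ti$total, 1L)
    p <- .index_to_pos(idx, ti)
    ctg <- p$contig; pos0 <- p$pos0
    seq <- refseq[[ctg]]
    is_indel <- stats::runif(1L) < 0.1
    pos <- pos0 + 1L
    if (!is_indel) {
      rb <- substr(seq, pos, pos)
      ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
      ref <- rb; alt <- ab
    } else if (stats::runif(1L) < 0.5) {  # deletion
      len <- sample(1:3, 1L)
      if (pos + len > nchar(seq)) next
      ref <- substr(seq, pos, pos + len)
      alt <- substr(seq, pos, pos)
    } else {                              # insertion
      len <- sample(1:3, 1L)
      ref <- substr(seq, pos, pos)
      alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
    }
    v <- .normalize_one(ctg, pos, ref, alt, refseq)
    key <- paste(ctg, v$pos, v$ref, v$alt, sep = ":")
    if (key %in% exclude) next
    if (length(rows) && key %in% vapply(rows, `[[`, character(1), "key"))
      next
    rows[[length(rows) + 1L]] <- list(contig = ctg, pos = v$pos,
                                      ref = v$ref, alt = v$alt, key = key)
  }
  if (!length(rows))
    return(cbind(.empty_calls("truth")[0, 1:4],
                 data.frame(mq = numeric(0), gt = character(0),
                            damaging = logical(0), known = logical(0))))
  df <- data.frame(
    contig = vapply(rows, `[[`, character(1), "contig"),
    pos = vapply(rows, `[[`, numeric(1), "pos"),
    ref = vapply(rows, `[[`, character(1), "ref"),
    alt = vapply(rows, `[[`, character(1), "alt"),
    stringsAsFactors = FALSE)
  df$pos <- as.integer(df$pos)
  df$mq <- ifelse(stats::runif(nrow(df)) < cfg$low_mq_frac, 22, 60)
  df$gt <- sample(c("0/1", "1/1"), nrow(df), replace = TRUE,
                  prob = c(0.6, 0.4))
  df$damaging <- stats::runif(nrow(df)) < cfg$damaging_frac
  df$known <- stats::runif(nrow(df)) < cfg$known_frac
  df
}

.draw_coverage <- function(assets, cfg) {
  rows <- list()
  for (i in seq_len(nrow(assets$targets))) {
    s <- assets$targets$start[i]; e <- assets$targets$end[i]
    starts <- seq(s, e - 1L, by = .SIM_COV_BLOCK)
    ends <- pmin(starts + .SIM_COV_BLOCK, e)
    d <- if (cfg$depth_dispersion == 0) {
      rep(as.integer(round(cfg$mean_depth)), length(starts))
    } else {
      stats::rnbinom(length(starts), mu = cfg$mean_depth,
                     size = cfg$depth_dispersion)
    }
    rows[[i]] <- data.frame(contig = assets$targets$contig[i],
                            start = starts, end = ends, depth = as.integer(d),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$contig, out$start), , drop = FALSE]
}

.depth_at <- function(cov, contig, pos0) {
  if (!length(contig)) return(integer(0))
  vapply(seq_along(contig), function(i) {
    sub <- cov[cov$contig == contig[i] & cov$start <= pos0[i] &
                 cov$end > pos0[i], "depth"]
    if (length(sub)) sub[1L] else 0L
  }, integer(1))
}

.draw_spanning_reads <- function(assets, cfg, cov, gt_now, sid) {
  cat <- assets$msat_catalog
  refseq <- assets$reference
  rl <- cfg$read_length
  out <- list()
  for (k in seq_len(nrow(cat))) {
    locus <- cat[k, ]
    g <- gt_now[gt_now$locus_id == locus$locus_id, , drop = FALSE]
    alleles <- c(g$a1[1L], g$a2[1L])
    tract_len <- locus$end - locus$start
    mlen <- nchar(locus$motif)
    n_reads <- .depth_at(cov, locus$contig, locus$start)
    if (n_reads <= 0L) next
    n_reads <- min(n_reads, 400L)
    seq <- refseq[[locus$contig]]
    for (r in seq_len(n_reads)) {
      allele <- alleles[sample(1:2, 1L)]
      obs <- allele
      if (stats::runif(1L) < cfg$stutter_prob)
        obs <- max(1L, obs + sample(c(-1L, 1L), 1L))
      d_units <- obs - locus$ref_repeat_count
      d_bp <- d_units * mlen
      max_off <- rl - tract_len - max(0L, d_bp) - 6L
      if (max_off < 6L) next
      offset <- sample(6:max_off, 1L)
      rstart0 <- locus$start - offset
      if (rstart0 < 0L) next
      ins_at <- offset + tract_len %/% 2L
      if (d_bp == 0L) {
        cigar <- paste0(rl, "M")
        footprint <- rl
        rseq <- substr(seq, rstart0 + 1L, rstart0 + rl)
      } else if (d_bp > 0L) {
        cigar <- paste0(ins_at, "M", d_bp, "I", rl - ins_at - d_bp, "M")
        footprint <- rl - d_bp
        fr <- substr(seq, rstart0 + 1L, rstart0 + footprint)
        rseq <- paste0(substr(fr, 1L, ins_at),
                       strrep(locus$motif, d_units),
                       substr(fr, ins_at + 1L, footprint))
      } else {
        cigar <- paste0(ins_at, "M", -d_bp, "D", rl - ins_at, "M")
        footprint <- rl - d_bp
        fr <- substr(seq, rstart0 + 1L, rstart0 + footprint)
        rseq <- paste0(substr(fr, 1L, ins_at),
                       substr(fr, ins_at - d_bp + 1L, footprint))
      }
      if (rstart0 + footprint < locus$end + 4L) next
      out[[length(out) + 1L]] <- data.frame(
        qname = sprintf("rd_%s_%06d_%04d", sid, k, r),
        contig = locus$contig, pos = rstart0 + 1L, cigar = cigar,
        seq = rseq, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(qname = character(), contig = character(),
                      pos = integer(), cigar = character(),
                      seq = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Run the full simulation from a configuration
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; if given, all study files are
#'   written there via [write_simulated_study()].
#' @return a \code{sim_study} object.
#' @export
simulate_study <- function(config = sim_config(), dir = NULL) {
  assets <- build_reference(config)
  study <- simulate_timepoints(assets)
  if (!is.null(dir)) write_simulated_study(study, dir)
  study
}

#' Write a simulated study to disk
#'
#' Emits reference.fa, genes.gff3, targets.bed, msat_catalog.tsv,
#' known_variants.tsv, per-sample VCF/coverage BED/spanning-read SAM files,
#' truth tables and a sample manifest. Output is byte-deterministic given
#' the configuration.
#'
#' @param study a \code{sim_study} object.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_simulated_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  assets <- study$assets
  write_reference_fasta(assets$reference, file.path(dir, "reference.fa"))
  write_gene_models(assets$genes, file.path(dir, "genes.gff3"))
  write_targets(assets$targets, file.path(dir, "targets.bed"))
  write_msat_catalog(assets$msat_catalog, file.path(dir, "msat_catalog.tsv"))
  kk <- study$known_keys
  km <- do.call(rbind, strsplit(kk, ":", fixed = TRUE))
  kdf <- if (length(kk)) {
    data.frame(contig = km[, 1L], pos = as.integer(km[, 2L]),
               ref = km[, 3L], alt = km[, 4L], stringsAsFactors = FALSE)
  } else {
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  }
  kdf <- kdf[order(kdf$contig, kdf$pos, kdf$ref, kdf$alt), , drop = FALSE]
  utils::write.table(kdf, file.path(dir, "known_variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list()
  for (s in study$samples) {
    write_vcf(s$calls, file.path(dir, paste0(s$sample_id, ".vcf")))
    write_coverage(s$coverage,
                   file.path(dir, paste0(s$sample_id, ".coverage.bed")))
    write_sam_reads(s$reads, assets$reference,
                    file.path(dir, paste0(s$sample_id, ".reads.sam")))
    manifest[[length(manifest) + 1L]] <- data.frame(
      sample_id = s$sample_id, individual = s$individual, age = s$age,
      vcf = paste0(s$sample_id, ".vcf"),
      coverage = paste0(s$sample_id, ".coverage.bed"),
      reads = paste0(s$sample_id, ".reads.sam"), stringsAsFactors = FALSE)
  }
  utils::write.table(do.call(rbind, manifest), file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  tv <- study$truth$variants
  utils::write.table(tv, file.path(dir, "truth_variants.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$msat_genotypes,
                     file.path(dir, "truth_msat_genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$msat_changes,
                     file.path(dir, "truth_msat_changes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Truth variant keys present for an individual at a given age
#'
#' @param truth the \code{truth} element of a \code{sim_study} (or the
#'   study itself).
#' @param individual individual identifier.
#' @param age sampling age in years.
#' @return character vector of variant keys.
#' @export
truth_keys_at <- function(truth, individual, age) {
  if (inherits(truth, "sim_study")) truth <- truth$truth
  vt <- truth$variants
  vt <- vt[vt$individual == individual, , drop = FALSE]
  present <- (vt$origin == "baseline" |
                (!is.na(vt$acquired_by) & vt$acquired_by <= age)) &
    (is.na(vt$lost_by) | vt$lost_by > age)
  variant_key(vt[present, , drop = FALSE])
}
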