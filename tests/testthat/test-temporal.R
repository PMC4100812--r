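test_that("depth/MQ filter boundary semantics: depth inclusive, MQ strict", {
  calls <- make_calls("c1", c(10, 20, 30), "A", "T",
                      depth = c(5, 4, 10), mq = c(31, 60, 30))
  kept <- filter_calls(calls, filter_params(min_depth = 5, min_mq = 30))
  expect_equal(kept$pos, 10)
  expect_equal(sum(attr(kept, "removed")), 2)
  empty <- filter_calls(make_calls("c1", integer(0), character(0),
                                   character(0))[0, ], filter_params())
  expect_equal(nrow(empty), 0)
})

test_that("filter agrees with a brute-force predicate scan on 1000 calls", {
  set.seed(5)
  n <- 1000
  calls <- make_calls("c1", seq_len(n), "A", "T",
                      depth = sample(0:20, n, replace = TRUE),
                      mq = sample(20:60, n, replace = TRUE))
  params <- filter_params(min_depth = 5, min_mq = 30)
  kept <- filter_calls(calls, params)
  oracle <- logical(n)
  for (i in seq_len(n))
    oracle[i] <- calls$depth[i] >= 5 && calls$mq[i] > 30
  expect_equal(kept$pos, calls$pos[oracle])
})

test_that("callable intersection is the depth-thresholded overlap", {
  a <- cov_track("chr1", 0, 100, 10)
  b <- cov_track("chr1", 50, 150, 10)
  res <- callable_intersection(a, b, 5)
  expect_equal(res$callable_bp, 50)
  expect_equal(c(res$intervals$start, res$intervals$end), c(50, 100))
  b4 <- cov_track("chr1", 0, 200, 4)
  expect_equal(callable_intersection(a, b4, 5)$callable_bp, 0)
})

test_that("callable intersection equals a positionwise brute-force scan", {
  set.seed(9)
  rand_track <- function() {
    starts <- sort(sample(0:900, 100))
    ends <- pmin(starts + sample(1:9, 100, replace = TRUE), 1000)
    # drop overlaps to satisfy the track invariant
    keep <- c(TRUE, starts[-1] >= cummax(ends[-100]))
    cov_track("chr1", starts[keep], ends[keep],
              sample(0:10, sum(keep), replace = TRUE))
  }
  for (rep in 1:3) {
    a <- rand_track(); b <- rand_track()
    res <- callable_intersection(a, b, 5)
    oracle <- brute_callable_positions(a, b, 5, "chr1", 1000)
    got <- unlist(lapply(seq_len(nrow(res$intervals)), function(i)
      seq(res$intervals$start[i], res$intervals$end[i] - 1L)))
    if (is.null(got)) got <- integer(0)
    expect_equal(sort(got), oracle, ignore_attr = TRUE)
    expect_equal(res$callable_bp, length(oracle))
  }
})

test_that("diff partitions variants by set algebra over callable loci", {
  cov <- cov_track("c1", 0, 1000, 50)
  e <- exome_sample("s1", 20, make_calls("c1", c(10, 20), "A", "T"), cov)
  l <- exome_sample("s2", 30, make_calls("c1", c(20, 30), "A", "T"), cov)
  d <- diff_timepoints(e, l)
  expect_equal(d$acquired, "c1:30:A:T")
  expect_equal(d$lost, "c1:10:A:T")
  expect_equal(d$persistent, "c1:20:A:T")
  expect_equal(d$n_differing, 2)
  expect_equal(d$shared_fraction, 1 / 3)
  # identical sets
  d2 <- diff_timepoints(e, exome_sample("s3", 40, e$calls, cov))
  expect_equal(d2$n_differing, 0)
  expect_equal(d2$shared_fraction, 1)
  expect_error(diff_timepoints(e, e), "same sample")
})

test_that("variants outside the callable intersection become unverifiable", {
  cov_a <- cov_track("c1", 0, 1000, 50)
  cov_b <- rbind(cov_track("c1", 0, 25, 50), cov_track("c1", 25, 1000, 3))
  e <- exome_sample("s1", 20, make_calls("c1", c(10, 200), "A", "T"), cov_a)
  l <- exome_sample("s2", 30, make_calls("c1", 10, "A", "T"), cov_b)
  d <- diff_timepoints(e, l)
  expect_equal(d$unverifiable, "c1:200:A:T")
  expect_equal(d$persistent, "c1:10:A:T")
  expect_length(d$lost, 0)
  expect_equal(d$callable_bp, 25)
})

test_that("swapping sample order swaps acquired and lost", {
  cov <- cov_track("c1", 0, 1000, 50)
  x <- make_calls("c1", c(10, 20), "A", "T")
  y <- make_calls("c1", c(20, 30), "A", "T")
  d1 <- diff_timepoints(exome_sample("a", 20, x, cov),
                        exome_sample("b", 30, y, cov))
  d2 <- diff_timepoints(exome_sample("c", 20, y, cov),
                        exome_sample("d", 30, x, cov))
  expect_equal(d1$acquired, d2$lost)
  expect_equal(d1$lost, d2$acquired)
  expect_equal(d1$persistent, d2$persistent)
})

test_that("raising thresholds never increases callable bp or differences", {
  st <- small_study()
  # make coverage variable for this check
  cfg <- small_config(depth_dispersion = 2, mean_depth = 20, seed = 21L)
  stv <- simulate_study(cfg)
  ids <- names(stv$samples)
  s1 <- stv$samples[[ids[1]]]; s2 <- stv$samples[[ids[2]]]
  prev_bp <- Inf; prev_diff <- Inf
  for (md in c(1, 5, 10, 20)) {
    p <- filter_params(min_depth = md, min_verify_reads = md)
    d <- diff_timepoints(exome_sample(s1$sample_id, s1$age, s1$calls,
                                      s1$coverage),
                         exome_sample(s2$sample_id, s2$age, s2$calls,
                                      s2$coverage), p)
    expect_lte(d$callable_bp, prev_bp)
    expect_lte(d$n_differing, prev_diff)
    prev_bp <- d$callable_bp; prev_diff <- d$n_differing
  }
})

test_that("noise-off detection recovers the truth partition exactly", {
  st <- small_study()
  tv <- st$truth$variants
  for (ind in c("indA", "indB")) {
    ages <- st$assets$config$ages[[ind]]
    s1 <- st$samples[[paste0(ind, "_y", ages[1])]]
    s2 <- st$samples[[paste0(ind, "_y", ages[2])]]
    d <- diff_timepoints(
      exome_sample(s1$sample_id, s1$age, s1$calls, s1$coverage),
      exome_sample(s2$sample_id, s2$age, s2$calls, s2$coverage))
    k1 <- truth_keys_at(st$truth, ind, ages[1])
    k2 <- truth_keys_at(st$truth, ind, ages[2])
    callable <- function(keys) {
      sub <- tv[match(keys, variant_key(tv)), , drop = FALSE]
      keep <- vapply(seq_len(nrow(sub)), function(i) {
        s <- sub$pos[i] - 1L
        e2 <- s + nchar(sub$ref[i])
        iv <- d$callable_intervals
        any(iv$contig == sub$contig[i] & iv$start <= s & iv$end >= e2)
      }, logical(1))
      keys[keep]
    }
    expect_setequal(d$acquired, callable(setdiff(k2, k1)))
    expect_setequal(d$lost, callable(setdiff(k1, k2)))
    expect_setequal(d$persistent, callable(intersect(k1, k2)))
    # partition: disjoint union of the callable keys of both samples
    expect_length(intersect(d$acquired, d$lost), 0)
    expect_length(intersect(d$acquired, d$persistent), 0)
    expect_setequal(c(d$acquired, d$lost, d$persistent),
                    union(callable(k1), callable(k2)))
  }
})

test_that("a variant acquired then lost appears only in the first diff", {
  cov <- cov_track("c1", 0, 1000, 50)
  base <- make_calls("c1", 10, "A", "T")
  with_var <- make_calls("c1", c(10, 500), "A", "T")
  s <- list(exome_sample("t1", 42, base, cov),
            exome_sample("t2", 51, with_var, cov),
            exome_sample("t3", 57, base, cov))
  series <- multi_timepoint_series(s)
  expect_length(series, 2)
  expect_equal(series[[1]]$acquired, "c1:500:A:T")
  expect_length(series[[2]]$acquired, 0)
  expect_error(multi_timepoint_series(s[1]), "at least 2")
})

test_that("genotype-state changes count as differing only when enabled", {
  cov <- cov_track("c1", 0, 1000, 50)
  e <- exome_sample("s1", 20, make_calls("c1", 10, "A", "T", gt = "0/1"),
                    cov)
  l <- exome_sample("s2", 30, make_calls("c1", 10, "A", "T", gt = "1/1"),
                    cov)
  d_off <- diff_timepoints(e, l)
  expect_equal(d_off$n_differing, 0)
  d_on <- diff_timepoints(e, l, count_genotype_changes = TRUE)
  expect_equal(d_on$n_differing, 1)
  expect_equal(d_on$genotype_changed, "c1:10:A:T")
})
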