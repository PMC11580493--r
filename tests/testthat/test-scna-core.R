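test_that("alignment filtering enforces MAPQ, duplicate and pairing rules", {
  rec <- function(qname, flag, mapq, pos = 100, mpos = 300)
    data.frame(qname = qname, flag = flag, chrom = "1", pos = pos,
               mapq = mapq, mpos = mpos, stringsAsFactors = FALSE)
  records <- rbind(
    rec("q59", 99L, 59),            # MAPQ 59 -> removed (strict < 60)
    rec("q60", 99L, 60),            # MAPQ 60 -> retained
    rec("dup", 99L + 1024L, 60),    # duplicate -> removed
    rec("sec", 99L + 256L, 60),     # secondary -> removed
    rec("unp", 0L, 60),             # unpaired/improper -> removed
    rec("unm", 99L + 4L, 60))       # unmapped -> removed

  out <- filter_alignments(records, min_mapq = 60)
  expect_equal(out$records$qname, "q60")
  expect_equal(out$tallies$total_records, 6L)
  expect_equal(out$tallies$mapped_records, 5L)
  expect_equal(out$tallies$filtered_records, 1L)
  expect_equal(out$tallies$filtered_pairs, 1L)

  empty <- filter_alignments(records[0, ])
  expect_equal(nrow(empty$records), 0L)
  expect_equal(empty$tallies$total_records, 0L)
})

test_that("pairs are counted once, in the bin of the leftmost mate start", {
  grid <- toy_grid(11e6)
  # pairs with leftmost starts at 0-based 0, 1, 5500000 -> counts [2, 1]
  pairs <- data.frame(
    qname = c("a", "b", "c"), chrom = "1",
    pos1 = c(1L, 2L, 5500001L),       # SAM 1-based
    pos2 = c(201L, 202L, 5500201L),
    mapq = 60L, dup = FALSE)
  sam <- write_test_sam(tempfile(fileext = ".sam"), c("1" = 11e6), pairs)
  records <- read_alignments(sam)
  expect_equal(nrow(records), 6L)     # both mates loaded
  filt <- filter_alignments(records)
  expect_equal(filt$tallies$filtered_pairs, 3L)
  counts <- count_pairs_in_bins(filt, grid)
  expect_equal(counts$counts, c(2, 1))
  expect_equal(attr(counts, "dropped"), 0L)

  # empty stream -> all-zero counts
  empty <- filter_alignments(records[0, ])
  expect_equal(count_pairs_in_bins(empty, grid)$counts, c(0, 0))

  # unknown chromosome -> dropped with warning, counts unchanged
  recs2 <- records
  recs2$chrom[recs2$qname == "c"] <- "17"
  filt2 <- filter_alignments(recs2)
  expect_warning(c2 <- count_pairs_in_bins(filt2, grid), "17")
  expect_equal(c2$counts, c(2, 0))
  expect_equal(attr(c2, "dropped"), 1L)
})

test_that("GC/mappability correction flattens a known injected bias", {
  set.seed(42)
  grid <- build_bin_grid(c("1" = 5.5e6 * 200), bin_size = 5.5e6)
  grid$gc <- stats::runif(200, 0.3, 0.6)
  grid$mappability <- stats::runif(200, 0.7, 1)
  bias <- gc_bias_curve(grid$gc) * grid$mappability
  raw <- bin_counts("biased", round(2000 * bias))

  for (method in c("median_bins", "loess")) {
    corr <- correct_counts(raw, grid, method = method)
    cv <- stats::sd(corr$counts) / mean(corr$counts)
    expect_lt(cv, if (method == "loess") 0.02 else 0.06)
  }

  # the two methods agree downstream within 0.05 log2 per bin
  p_lo <- to_log2_profile(correct_counts(raw, grid, "loess"), grid)
  p_md <- to_log2_profile(correct_counts(raw, grid, "median_bins"), grid)
  expect_lt(max(abs(p_lo$log2r - p_md$log2r), na.rm = TRUE), 0.05)

  # constant annotations: corrected = raw up to a global constant
  gflat <- flat_annotation(toy_grid(5.5e6 * 4, bin = 5.5e6))
  rawf <- bin_counts("flat", c(100, 150, 200, 250))
  corrf <- correct_counts(rawf, gflat, "median_bins")
  expect_equal(corrf$counts / corrf$counts[1], c(100, 150, 200, 250) / 100)

  # loess falls back below 30 usable bins
  expect_warning(correct_counts(rawf, gflat, "loess"), "median_bins")
})

test_that("log2 profiles are median-normalized, floored and scale-invariant", {
  grid <- flat_annotation(build_bin_grid(c("1" = 22e6), bin_size = 5.5e6))

  # corrected [100,100,100,200] -> median 100 -> log2r [0,0,0,1]
  p <- to_log2_profile(bin_counts("s", c(100, 100, 100, 200), stage = "corrected"), grid)
  expect_equal(p$log2r, c(0, 0, 0, 1))

  # constant counts -> all zero
  pc <- to_log2_profile(bin_counts("s", rep(7, 4), stage = "corrected"), grid)
  expect_equal(pc$log2r, rep(0, 4))

  # scaling all counts by 7 changes nothing
  p7 <- to_log2_profile(bin_counts("s", 7 * c(100, 100, 100, 200), stage = "corrected"), grid)
  expect_equal(p7$log2r, p$log2r)

  # zero-count bin floors at log2(2^-8) = -8
  pz <- to_log2_profile(bin_counts("s", c(100, 100, 100, 0), stage = "corrected"), grid)
  expect_equal(pz$log2r[4], -8)

  expect_error(to_log2_profile(bin_counts("s", rep(0, 4), stage = "corrected"), grid),
               "insufficient coverage")
})

test_that("sex chromosomes are excluded from the median and scoring by default", {
  sizes <- c("1" = 11e6, "X" = 11e6)
  grid <- flat_annotation(build_bin_grid(sizes, bin_size = 5.5e6))
  # male-like X at half depth must not shift the autosomal median or be called
  counts <- bin_counts("m", c(100, 100, 50, 50), stage = "corrected")
  p <- call_aberrant(to_log2_profile(counts, grid))
  expect_equal(p$log2r[1:2], c(0, 0))
  expect_equal(p$calls, c(0L, 0L, 0L, 0L))
  m <- compute_metrics(p)
  expect_equal(m$aberrant_bin_count, 0L)

  # opting in includes X bins in scoring
  p_in <- call_aberrant(to_log2_profile(counts, grid, include_sex_chromosomes = TRUE))
  expect_true(any(p_in$calls[3:4] != 0L))
})

test_that("aberration calls use strict inequalities at +/-0.1", {
  vals <- c(0.11, -0.11, 0, 0.1, -0.1, 0.1000001, NA)
  p <- profile_from_log2(vals)
  expect_equal(p$calls, c(1L, -1L, 0L, 0L, 0L, 1L, 0L))
})

test_that("metrics match hand-computed and brute-force values", {
  # per-bin example: called bins {0.25, -0.30, 0.11}
  m <- compute_metrics(profile_from_log2(c(0.25, -0.30, 0.05, 0.11, -0.08, 0.10)))
  expect_equal(m$cni_score, 0.66)
  expect_equal(m$aberrant_bin_count, 3L)
  expect_false(m$scna_positive)
  expect_equal(m$tumor_fraction_score, 0.22)

  # all-neutral profile
  m0 <- compute_metrics(profile_from_log2(rep(0, 10)))
  expect_equal(m0$cni_score, 0)
  expect_equal(m0$aberrant_bin_count, 0L)
  expect_false(m0$scna_positive)
  expect_true(is.na(m0$tumor_fraction_score))

  # exactly 5 aberrant bins of |log2r| 0.2: positive, cni 1.0, fraction 0.2
  m5 <- compute_metrics(profile_from_log2(c(rep(0.2, 5), rep(0, 20))))
  expect_true(m5$scna_positive)
  expect_equal(m5$cni_score, 1.0)
  expect_equal(m5$tumor_fraction_score, 0.2)
  # one fewer is negative
  expect_false(compute_metrics(profile_from_log2(c(rep(0.2, 4), rep(0, 20))))$scna_positive)
})

test_that("compute_metrics agrees with the naive per-bin oracle on random profiles", {
  set.seed(123)
  for (i in 1:25) {
    log2r <- stats::rnorm(1000, sd = 0.2)
    log2r[sample(1000, 50)] <- NA
    m <- compute_metrics(profile_from_log2(log2r))
    o <- naive_metrics(log2r)
    expect_equal(m$cni_score, o$cni_score, tolerance = 1e-12)
    expect_identical(m$aberrant_bin_count, o$aberrant_bin_count)
    expect_identical(m$scna_positive, o$scna_positive)
    expect_equal(m$tumor_fraction_score, o$tumor_fraction_score, tolerance = 1e-12)
  }
})

test_that("fraction score exceeds 0.1 whenever defined and ignores aberration burden", {
  set.seed(7)
  for (i in 1:50) {
    m <- compute_metrics(profile_from_log2(stats::rnorm(300, sd = 0.15)))
    if (!is.na(m$tumor_fraction_score)) expect_gt(m$tumor_fraction_score, 0.1)
  }
  # duplicating every aberrant segment doubles cni and count, not the fraction
  base <- c(0.3, -0.25, 0.18, rep(0, 10))
  m1 <- compute_metrics(profile_from_log2(base))
  m2 <- compute_metrics(profile_from_log2(c(base, base)))
  expect_equal(m2$cni_score, 2 * m1$cni_score)
  expect_equal(m2$aberrant_bin_count, 2L * m1$aberrant_bin_count)
  expect_equal(m2$tumor_fraction_score, m1$tumor_fraction_score)
})

test_that("profiles and metrics are invariant to sequencing depth", {
  grid <- annotated_hg19_grid()
  raw <- simulate_counts(sim_spec(template_profile("oligo_1p19q"), 0.4, seed = 3), grid)
  res1 <- run_sample(raw, grid)
  raw5 <- bin_counts(raw$sample_id, raw$counts * 5)
  res5 <- run_sample(raw5, grid)
  expect_equal(res5$profile$log2r, res1$profile$log2r, tolerance = 1e-10)
  expect_identical(res5$profile$calls, res1$profile$calls)
  expect_equal(res5$metrics$cni_score, res1$metrics$cni_score, tolerance = 1e-10)
  expect_identical(res5$metrics$aberrant_bin_count, res1$metrics$aberrant_bin_count)
})

test_that("QC metrics follow their definitions", {
  qc <- qc_metrics(total_reads = 42e6, mapped_reads = 40e6,
                   filtered_pairs = 20e6, read_length = 75,
                   genome_size = 3.1e9)
  expect_equal(qc$mapped_fraction, 40 / 42)
  expect_equal(qc$mean_coverage_depth, 20e6 * 2 * 75 / 3.1e9)
  expect_equal(round(qc$mean_coverage_depth, 2), 0.97)

  expect_equal(qc_metrics(10, 10, 5)$mapped_fraction, 1)
  expect_equal(qc_metrics(10, 8, 0)$mean_coverage_depth, 0)
  expect_true(is.na(qc_metrics(0, 0, 0)$mapped_fraction))
  expect_error(qc_metrics(10, 11, 0), "exceeds")
})
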