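test_that("window counting assigns fragments to every overlapped window", {
  g <- genome_spec(c("chr1", "chrM"), c(5000, 500), mito_names = "chrM")
  fc <- frags(g, "chr1", 100L, 200L, "A")
  wc <- aggregate_windows(fc, width = 1000, step = 1000)
  expect_equal(wc$counts[wc$windows$chrom == "chr1"], c(1L, 0L, 0L, 0L, 0L))

  spanning <- frags(g, "chr1", 900L, 1100L, "A")
  wc2 <- aggregate_windows(spanning, width = 1000, step = 1000)
  expect_equal(wc2$counts[wc2$windows$chrom == "chr1"],
               c(1L, 1L, 0L, 0L, 0L))
  expect_error(aggregate_windows(fc, width = 0), "positive")
  expect_error(aggregate_windows(fc, width = 100, step = 200), "step")
})

test_that("window counts equal the brute-force overlap oracle", {
  g <- tiny_genome(20000L)
  for (seed in 1:3) {
    fc <- random_instance(g, 800L, 4L, seed = seed)
    wc <- aggregate_windows(fc, width = 700, step = 700)
    qf <- qualified_fragments(fc)
    oracle <- bf_count_overlaps(as.data.frame(wc$windows),
                                as.data.frame(qf$records))
    expect_identical(wc$counts, oracle)
  }
})

test_that("Poisson tail p-values match the closed-form series", {
  # P(Poisson(1) >= 10) summed directly over the tail (summing the tail
  # avoids the catastrophic cancellation of 1 - sum_{k<10})
  closed_form <- sum(exp(-1) / factorial(10:60))
  g <- genome_spec("chr1", 10000)
  # 10 fragments in one window; calibrate so lambda = 1:
  # lambda = total * width / egs = 10 * 1000 / 10000 = 1
  fc <- frags(g, "chr1", 100L + 0:9, 150L + 0:9, rep("A", 10))
  wc <- aggregate_windows(fc, width = 1000, step = 1000)
  expect_equal(wc$counts[1], 10L)
  pk <- call_peaks(wc, q_max = 1, min_fold = 0)
  expect_equal(pk$p_value[1], closed_form, tolerance = 1e-10)
  expect_equal(closed_form, 1.114255e-07, tolerance = 1e-6)
})

test_that("zero-count windows are never significant", {
  g <- genome_spec("chr1", 10000)
  fc <- frags(g, "chr1", 0L, 100L, "A")
  wc <- aggregate_windows(fc, width = 1000, step = 1000)
  pk <- call_peaks(wc, q_max = 1.0, min_fold = 0)
  # only the single nonzero window can appear
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, 0L)
})

test_that("BH q-values equal the textbook step-up adjustment", {
  set.seed(99)
  p <- runif(100)^2
  expect_equal(stats::p.adjust(p, "BH"), bf_bh(p))
  # and inside the caller: single-window peaks inherit the BH q of their
  # window, computed over nonzero windows only
  g <- genome_spec("chr1", 50000)
  fc <- random_instance(genome_spec(c("chr1", "chrM"), c(50000, 100),
                                    mito_names = "chrM"),
                        500L, 3L, seed = 5)
  wc <- aggregate_windows(fc, width = 500, step = 500)
  lambda <- wc$total_fragments * wc$width / 50000
  nz <- which(wc$counts > 0)
  pvec <- ppois(wc$counts[nz] - 1, lambda, lower.tail = FALSE)
  qvec <- bf_bh(pvec)
  pk <- call_peaks(wc, q_max = 1, min_fold = 0, merge_gap = 0)
  single <- pk[pk$end - pk$start == 500L, ]
  idx <- match(single$start, wc$windows$start[nz])
  expect_equal(single$q_value, qvec[idx])
})

test_that("peak calls are sorted, disjoint, and respect both cutoffs", {
  sim <- simulate_dataset(simulation_config(
    n_cell_types = 1, cells_per_type = 10, fragments_per_cell = 1500,
    peaks_per_type = 20, shared_peak_fraction = 0, seed = 3))
  wc <- aggregate_windows(sim$fragments)
  pk <- call_peaks(wc, q_max = 0.01, min_fold = 2)
  expect_true(all(diff(pk$start) > 0))
  expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))
  expect_true(all(pk$q_value < 0.01))
  expect_true(all(pk$fold_change >= 2))
  # relaxing q_max only adds signal: every strict peak is contained in
  # some loose peak (boundaries may extend as more windows turn significant)
  pk_loose <- call_peaks(wc, q_max = 0.10, min_fold = 2)
  expect_gte(nrow(pk_loose), nrow(pk))
  contained <- vapply(seq_len(nrow(pk)), function(i) {
    any(pk_loose$chrom == pk$chrom[i] &
          pk_loose$start <= pk$start[i] & pk_loose$end >= pk$end[i])
  }, logical(1))
  expect_true(all(contained))
})

test_that("planted peaks are recovered with high precision and recall", {
  sim <- simulate_dataset(simulation_config(
    n_cell_types = 1, cells_per_type = 20, fragments_per_cell = 2000,
    peaks_per_type = 30, shared_peak_fraction = 0, seed = 21))
  wc <- aggregate_windows(sim$fragments)
  pk <- call_peaks(wc, q_max = 0.01)
  truth <- as.data.frame(sim$truth$peaks)
  recall <- mean(reciprocal_match(truth, as.data.frame(pk)))
  precision <- mean(reciprocal_match(as.data.frame(pk), truth))
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
})

test_that("doubling all window counts never decreases fold changes", {
  g <- tiny_genome(20000L)
  fc <- random_instance(g, 500L, 3L, seed = 8)
  wc <- aggregate_windows(fc, width = 1000, step = 1000)
  pk1 <- call_peaks(wc, q_max = 1, min_fold = 0, merge_gap = 0)
  wc2 <- wc
  wc2$counts <- wc$counts * 2L
  pk2 <- call_peaks(wc2, q_max = 1, min_fold = 0, merge_gap = 0)
  shared <- intersect(paste(pk1$chrom, pk1$start), paste(pk2$chrom, pk2$start))
  f1 <- pk1$fold_change[match(shared, paste(pk1$chrom, pk1$start))]
  f2 <- pk2$fold_change[match(shared, paste(pk2$chrom, pk2$start))]
  expect_true(all(f2 >= f1))
})

test_that("select_features dispatches across the three modes", {
  g <- genome_spec("chr1", 10000)
  bins <- select_features("bins", genome = g, bin_size = 5000)
  expect_equal(n_features(bins), 2L)
  expect_equal(bins$mode, "bins")

  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t200\t300", "chr1\t400\t500"), bed)
  custom <- select_features("custom", genome = g, bed_path = bed)
  expect_equal(n_features(custom), 3L)
  expect_equal(custom$mode, "custom")
  expect_error(select_features("custom", genome = g), "BED path")

  sim <- simulate_dataset(simulation_config(seed = 19))
  fs <- select_features("peaks", fragments = sim$fragments)
  n_planted <- nrow(sim$truth$peaks)
  expect_gte(n_features(fs), 0.8 * n_planted)
  expect_lte(n_features(fs), 1.2 * n_planted)
  # a pre-computed BED bypasses the internal caller
  pre <- select_features("peaks", genome = g, bed_path = bed)
  expect_equal(pre$mode, "peaks")
  expect_equal(n_features(pre), 3L)
})

test_that("peak overlap counting is per-a-peak", {
  a <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  b <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  expect_equal(count_overlapping_peaks(a, b), 1L)
  disj <- data.frame(chrom = "chr1", start = 500L, end = 600L)
  expect_equal(count_overlapping_peaks(a, disj), 0L)
  two_b <- data.frame(chrom = "chr1", start = c(10L, 60L),
                      end = c(40L, 90L))
  expect_equal(count_overlapping_peaks(a, two_b), 1L)
})

test_that("TSS-proximal fraction uses peak midpoints within d", {
  g <- genome_spec("chr1", 100000)
  peaks <- data.frame(chrom = "chr1", start = 900L, end = 1100L)
  tss <- feature_set(data.frame(chrom = "chr1", start = 1500L, end = 1501L),
                     genome = g)
  expect_equal(tss_proximal_fraction(peaks, tss, d = 2000), 1.0)
  expect_equal(tss_proximal_fraction(peaks, tss, d = 100), 0.0)
  expect_error(tss_proximal_fraction(peaks[0, ], tss), "empty")

  # random instance vs brute-force distance oracle
  set.seed(31)
  pk <- data.frame(chrom = "chr1",
                   start = sort(sample.int(90000, 40)))
  pk$end <- pk$start + 500L
  ts_start <- sample.int(99000, 25)
  ts <- feature_set(data.frame(chrom = "chr1", start = ts_start,
                               end = ts_start + 1L),
                    genome = g, validate = FALSE)
  for (d in c(100, 1000, 5000)) {
    mids <- (pk$start + pk$end) %/% 2
    oracle <- mean(vapply(mids, function(m)
      any(abs(m - ts$features$start) <= d), logical(1)))
    expect_equal(tss_proximal_fraction(pk, ts, d = d), oracle)
  }
})
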