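test_that("fragment counts and barcodes match the configuration", {
  cfg <- simulation_config(n_cell_types = 2, cells_per_type = 10,
                           fragments_per_cell = 1000, duplicate_rate = 0,
                           seed = 1)
  sim <- simulate_dataset(cfg)
  expect_equal(n_records(sim$fragments), 20000L)
  expect_equal(nrow(sim$truth$cells), 20L)
  expect_setequal(barcodes(sim$fragments), sim$truth$cells$barcode)
  # per-cell counts are exact
  percell <- sim$fragments$records[, .N, by = barcode]
  expect_true(all(percell$N == 1000L))
})

test_that("shared/specific peak bookkeeping follows the config", {
  cfg <- simulation_config(peaks_per_type = 100, shared_peak_fraction = 0.5,
                           n_cell_types = 2, cells_per_type = 2,
                           fragments_per_cell = 100, seed = 2)
  sim <- simulate_dataset(cfg)
  pk <- sim$truth$peaks
  expect_equal(nrow(pk), 150L)  # 50 shared + 50 + 50 specific
  expect_equal(sum(pk$shared), 50L)
  for (t in 1:2)
    expect_equal(nrow(truth_peaks_for_type(sim$truth, t)), 100L)
  # peaks are disjoint with the configured minimum gap
  expect_true(all(diff(pk$start) - (pk$end[-nrow(pk)] - pk$start[-nrow(pk)])
                  >= 0))
  gaps <- pk$start[-1] - pk$end[-nrow(pk)]
  expect_true(all(gaps[pk$chrom[-1] == pk$chrom[-nrow(pk)]] >=
                    cfg$min_peak_gap))
})

test_that("empirical fragment sizes match the analytic mixture mean", {
  cfg <- simulation_config(n_cell_types = 1, cells_per_type = 50,
                           fragments_per_cell = 2000, duplicate_rate = 0,
                           mito_fraction = 0, seed = 5)
  expect_equal(size_mixture_mean(cfg), 238.0)
  sim <- simulate_dataset(cfg)  # 1e5 fragments
  sizes <- sim$fragments$records[, end - start]
  mix_var <- with(cfg$size_mixture,
                  sum(weight * (mean^2 + sd^2)) - 238^2)
  se <- sqrt(mix_var / length(sizes))
  expect_lt(abs(mean(sizes) - 238.0), 3 * se)
  # sizes respect the truncation bounds
  expect_true(all(sizes >= 30 & sizes <= 1500))
})

test_that("per-cell FRiP against truth peaks matches the closed form", {
  cfg <- simulation_config(n_cell_types = 1, cells_per_type = 50,
                           fragments_per_cell = 2000, duplicate_rate = 0,
                           mito_fraction = 0, seed = 6)
  sim <- simulate_dataset(cfg)
  peaks <- feature_set(truth_peaks_for_type(sim$truth, 1),
                       mode = "peaks", genome = cfg$genome)
  frip <- compute_frip(sim$fragments, peaks)
  pooled <- sum(frip * 2000) / (50 * 2000)
  expected <- expected_frip(cfg)
  se <- sqrt(expected * (1 - expected) / (50 * 2000))
  expect_lt(abs(pooled - expected), 3 * se)
})

test_that("the QC duplicate-rate estimator recovers the configured rate", {
  cfg <- simulation_config(n_cell_types = 1, cells_per_type = 50,
                           fragments_per_cell = 2000, duplicate_rate = 0.01,
                           mito_fraction = 0, seed = 7)
  sim <- simulate_dataset(cfg)
  qc <- compute_cell_qc(sim$fragments)
  n <- sum(qc$total_fragments)
  est <- sum(qc$total_fragments - qc$dedup_fragments) / n
  se <- sqrt(0.01 * 0.99 / n)
  expect_lt(abs(est - 0.01), 3 * se)
})

test_that("the mitochondrial fraction estimator recovers the config", {
  cfg <- simulation_config(n_cell_types = 1, cells_per_type = 50,
                           fragments_per_cell = 2000, duplicate_rate = 0,
                           mito_fraction = 0.02, seed = 8)
  sim <- simulate_dataset(cfg)
  qc <- compute_cell_qc(sim$fragments)
  est <- sum(qc$mito_fraction * qc$total_fragments) / sum(qc$total_fragments)
  se <- sqrt(0.02 * 0.98 / sum(qc$total_fragments))
  expect_lt(abs(est - 0.02), 3 * se)
})

test_that("identical seeds reproduce the dataset bitwise", {
  cfg <- simulation_config(n_cell_types = 2, cells_per_type = 5,
                           fragments_per_cell = 500, seed = 9)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$fragments$records, s2$fragments$records)
  expect_identical(s1$truth$peaks, s2$truth$peaks)
  s3 <- simulate_dataset(simulation_config(
    n_cell_types = 2, cells_per_type = 5, fragments_per_cell = 500,
    seed = 10))
  expect_false(identical(s1$fragments$records, s3$fragments$records))
  # file-level determinism
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fragments(s1$fragments, file.path(d1, "f.tsv"))
  write_fragments(s2$fragments, file.path(d2, "f.tsv"))
  expect_identical(tools::md5sum(file.path(d1, "f.tsv"))[[1]],
                   tools::md5sum(file.path(d2, "f.tsv"))[[1]])
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(simulate_dataset(simulation_config(
    n_cell_types = 1, cells_per_type = 2, fragments_per_cell = 50,
    seed = 99)))
  expect_identical(runif(1), before)
})

test_that("truth manifests round-trip through disk", {
  cfg <- simulation_config(n_cell_types = 2, cells_per_type = 10,
                           fragments_per_cell = 100, seed = 11)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_truth(sim$truth, dir)
  expect_equal(nrow(data.table::fread(file.path(dir, "truth_cells.tsv"))),
               20L)
  back <- read_truth(dir)
  expect_equal(back$cells, sim$truth$cells)
  expect_equal(back$peaks,
               sim$truth$peaks[, list(chrom, start, end, peak_id,
                                      cell_types, shared)])
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(signal_fraction = 1.2), "\\[0, 1\\]")
  expect_error(simulation_config(
    size_mixture = data.frame(weight = c(0.5, 0.2), mean = c(100, 300),
                              sd = c(10, 20))), "sum to 1")
  # peaks that cannot fit without overlap
  expect_error(simulate_dataset(simulation_config(
    genome = genome_spec(c("c1", "chrM"), c(10000, 1000),
                         mito_names = "chrM"),
    peaks_per_type = 50, peak_width = 2000, seed = 1)), "cannot place")
})
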