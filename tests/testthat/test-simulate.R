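test_that("generators are pure functions of config and seed", {
  a <- simulate_arm_measurements(table1(), n_cells = 5, seed = 14)
  b <- simulate_arm_measurements(table1(), n_cells = 5, seed = 14)
  expect_identical(a, b)
  c <- simulate_arm_measurements(table1(), n_cells = 5, seed = 15)
  expect_false(identical(a$short_arm_um, c$short_arm_um))

  x <- simulate_flow_events(n_events = 1000, seed = 14)
  y <- simulate_flow_events(n_events = 1000, seed = 14)
  expect_identical(x, y)
})

test_that("zero noise reproduces the truth and telocentrics stay exact", {
  sim <- simulate_arm_measurements(table1(), n_cells = 4, noise_cv_pct = 0,
                                   cell_scale_sd_pct = 0, seed = 16)
  per_cell <- split(sim, sim$cell_id)
  truth_totals <- sort(rep(table1()$short_arm_um + table1()$long_arm_um,
                           each = 2))
  for (cell in per_cell)
    expect_equal(sort(cell$short_arm_um + cell$long_arm_um), truth_totals)
  expect_equal(sum(sim$short_arm_um == 0), 4 * 8)  # 4 cells x 8 telocentrics
})

test_that("arm noise has the configured magnitude", {
  truth <- data.frame(short_arm_um = 1, long_arm_um = 2)
  sim <- simulate_arm_measurements(truth, n_cells = 200, noise_cv_pct = 5,
                                   cell_scale_sd_pct = 0, seed = 17)
  cv <- 100 * stats::sd(sim$long_arm_um) / mean(sim$long_arm_um)
  expect_lt(abs(cv - 5), 1)
  expect_equal(mean(sim$long_arm_um), 2, tolerance = 0.02)
})

test_that("simulated flow components converge to the configured mixture", {
  x <- simulate_flow_events(n_events = 100000, ratio = 0.74,
                            cv_standard_pct = 3, cv_sample_pct = 3,
                            debris_fraction = 0, doublet_fraction = 0,
                            seed = 18)
  peaks <- detect_2c_peaks(x, n_peaks = 2)
  expect_equal(peaks$mean_fluorescence / c(370, 500), c(1, 1),
               tolerance = 0.01)
  expect_equal(peaks$cv_pct, c(3, 3), tolerance = 0.01)
})

test_that("near-zero CV peaks are detected within 0.5% of their means", {
  x <- simulate_flow_events(n_events = 10000, ratio = 0.74,
                            cv_standard_pct = 0.1, cv_sample_pct = 0.1,
                            debris_fraction = 0, doublet_fraction = 0,
                            seed = 3)
  peaks <- detect_2c_peaks(x, n_peaks = 2)
  expect_equal(peaks$mean_fluorescence / c(370, 500), c(1, 1),
               tolerance = 0.005)
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulate_flow_events(n_events = 50), ">= 100")
  expect_error(simulate_flow_events(ratio = -1), "positive")
  expect_error(simulate_flow_events(debris_fraction = 1.2), "\\[0, 1\\)")
  expect_error(simulate_flow_events(debris_fraction = 0.6,
                                    doublet_fraction = 0.5), "sum below 1")
  expect_error(simulate_arm_measurements(
    data.frame(short_arm_um = 2, long_arm_um = 1)), "invalid truth")
  expect_error(simulate_arm_measurements(table1(), noise_cv_pct = -1),
               "non-negative")
})

test_that("the pipeline recovers random karyotypes at low noise", {
  set.seed(19)
  for (i in 1:10) {
    truth <- random_true_karyotype(sample(4:15, 1))
    sim <- simulate_arm_measurements(truth, n_cells = 5, noise_cv_pct = 1,
                                     cell_scale_sd_pct = 2,
                                     seed = 1900 + i)
    k <- karyotype(sim, input = "cells")
    want <- table(factor(truth$levan_type, levels = levan_types))
    expect_identical(k$type_counts, 2L * c(want)[levan_types],
                     label = sprintf("karyotype %d type counts", i))
  }
})
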