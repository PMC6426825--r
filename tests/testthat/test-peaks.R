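test_that("histograms conserve events and localize mass", {
  h <- build_histogram(rep(250, 100), bins = 64, range = c(0, 500))
  expect_equal(sum(h$counts), 100)
  expect_equal(sum(h$counts > 0), 1L)

  set.seed(12)
  u <- runif(20000, 0, 100)
  h2 <- build_histogram(u, bins = 10, range = c(0, 100))
  expect_equal(sum(h2$counts), 20000)
  expect_true(all(abs(h2$counts / 20000 - 0.1) < 0.02))

  expect_error(build_histogram(numeric(0)), "no fluorescence events")
  expect_error(build_histogram(1:100, bins = 5), "at least 10")
  expect_error(build_histogram(c(-1, 2)), "non-negative")
})

test_that("a two-component mixture shows maxima at both component means", {
  set.seed(13)
  x <- c(rnorm(5000, 300, 9), rnorm(5000, 500, 15))
  peaks <- detect_2c_peaks(x, n_peaks = 2)
  expect_equal(peaks$mean_fluorescence, c(300, 500), tolerance = 0.01)
})

test_that("a single clean Gaussian peak is located within 1%", {
  x <- simulate_flow_events(n_events = 10000, ratio = 1, cv_standard_pct = 3,
                            cv_sample_pct = 3, debris_fraction = 0.05,
                            doublet_fraction = 0.02, seed = 21)
  peaks <- detect_2c_peaks(x, n_peaks = 1)
  expect_equal(nrow(peaks), 1L)
  expect_lt(abs(peaks$mean_fluorescence - 500) / 500, 0.01)
})

test_that("a mixed run returns exactly two non-overlapping 2C peaks", {
  x <- simulate_flow_events(n_events = 10000, ratio = 0.74, seed = 22)
  peaks <- detect_2c_peaks(x, n_peaks = 2)
  expect_equal(nrow(peaks), 2L)
  expect_false(attr(peaks, "overlap"))
  expect_true(all(peaks$window_low < peaks$mean_fluorescence))
  expect_true(all(peaks$mean_fluorescence < peaks$window_high))
})

test_that("G2/doublet populations are not reported as 2C peaks", {
  x <- simulate_flow_events(n_events = 20000, ratio = 0.74,
                            doublet_fraction = 0.05, seed = 23)
  peaks <- detect_2c_peaks(x, n_peaks = 2)
  expect_equal(peaks$mean_fluorescence, c(370, 500), tolerance = 0.01)
})

test_that("two true 2C peaks at an exact 2:1 ratio both survive", {
  # the doublet filter must not discard the standard peak when the sample
  # happens to sit at half its fluorescence
  x <- simulate_flow_events(n_events = 10000, ratio = 0.5,
                            doublet_fraction = 0.04, seed = 24)
  peaks <- detect_2c_peaks(x, n_peaks = 2)
  expect_equal(peaks$mean_fluorescence, c(250, 500), tolerance = 0.01)
})

test_that("detection fails loudly without a usable peak", {
  expect_error(detect_2c_peaks(rep(5, 1000), range = c(0, 100)),
               "no peak detected")
  x <- simulate_flow_events(n_events = 10000, ratio = 0.74, seed = 25)
  expect_error(detect_2c_peaks(x, n_peaks = 3), "expected 3 2C peak")
})

test_that("peak CV measures the gated coefficient of variation", {
  expect_equal(peak_cv(rep(100, 50), c(90, 110)), 0)
  set.seed(26)
  x <- rnorm(10000, 500, 15)
  expect_equal(peak_cv(x, c(500 - 60, 500 + 60)), 3, tolerance = 0.2 / 3)
  expect_error(peak_cv(c(1, 2, 3), c(10, 20)), "fewer than 2 events")
  expect_error(peak_cv(x, c(5, 2)), "low < high")
})
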