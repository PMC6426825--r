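test_that("the internal-standard ratio equation reproduces published rows", {
  expect_equal(round(estimate_2c_content(10.6, 14.9, 2.5), 2), 1.78)
  expect_equal(round(estimate_2c_content(10.5, 12.3, 2.5), 2), 2.13)
  expect_equal(estimate_2c_content(12, 12, 2.5), 2.5)
  expect_error(estimate_2c_content(-1, 10, 2.5), "positive")
  expect_error(estimate_2c_content(10, 0, 2.5), "positive")
})

test_that("the pg-to-bp conversion uses 0.978e9 bp per pg on the 1C value", {
  expect_equal(content_to_genome_size(1), 978)
  expect_equal(content_to_genome_size(0.5), 489)
  expect_equal(content_to_genome_size(1, unit = "bp"), 0.978e9)
  expect_equal(round(content_to_genome_size((10.6 / 14.9) * 2.5 / 2), 2),
               869.70)
})

test_that("estimate_2c_content is linear in N and X and inverse in M", {
  expect_equal(estimate_2c_content(20, 10, 2.5),
               2 * estimate_2c_content(10, 10, 2.5))
  expect_equal(estimate_2c_content(10, 10, 5),
               2 * estimate_2c_content(10, 10, 2.5))
  expect_equal(estimate_2c_content(10, 20, 2.5),
               estimate_2c_content(10, 10, 2.5) / 2)
})

test_that("the published peak-means table reproduces its own summary", {
  printed <- table2_printed()
  gs <- genome_size(peak_means = urechis_flow_peaks())
  r <- gs$replicates
  expect_equal(round(r$ratio, 2), printed$ratio)
  # per-row DNA content and size within the uncertainty propagated from the
  # one-decimal rounding of the printed peak means
  tol_mb <- r$size_mb * 0.05 * (1 / r$N + 1 / r$M)
  expect_true(all(abs(r$size_mb - printed$mb) <= tol_mb))
  expect_equal(gs$aggregate$mean_ratio, mean(r$N / r$M))
  expect_equal(round(gs$aggregate$mean_ratio, 2), 0.74)
  expect_equal(round(gs$aggregate$mean_pg_2c, 2), 1.85)
  expect_equal(round(gs$aggregate$sem_size_mb, 2), 20.21)
})

test_that("aggregation matches direct mean and SEM formulas", {
  gs <- genome_size(peak_means = urechis_flow_peaks())
  r <- gs$replicates
  expect_identical(gs$aggregate$mean_size_mb, mean(r$size_mb))
  expect_identical(gs$aggregate$sem_size_mb,
                   stats::sd(r$size_mb) / sqrt(nrow(r)))
  one <- genome_size(peak_means = data.frame(M = 14.9, N = 10.6))
  expect_equal(one$aggregate$sem_pg_2c, 0)
  ten <- genome_size(peak_means = data.frame(M = rep(14.9, 10),
                                             N = rep(10.6, 10)))
  expect_equal(ten$aggregate$sem_ratio, 0)
  expect_error(aggregate_replicates(data.frame()), "no replicates")
})

test_that("an identity peak ratio returns the standard's DNA content", {
  gs <- genome_size(peak_means = data.frame(M = 500, N = 500))
  expect_equal(gs$replicates$pg_2c, 2.5)
  expect_equal(gs$replicates$size_mb, 978 * 1.25)
})

test_that("replicate analysis recovers a simulated mixture", {
  x <- simulate_flow_events(n_events = 10000, ratio = 0.74, seed = 7)
  rep1 <- analyze_replicate(x, standard = 2.5)
  expect_lt(abs(rep1$pg_2c - 1.85) / 1.85, 0.02)
  expect_true(rep1$qc_pass)
  expect_lt(rep1$cv_standard, 5)
})

test_that("high-CV acquisitions are flagged but still estimated", {
  x <- simulate_flow_events(n_events = 10000, ratio = 0.74,
                            cv_standard_pct = 8, cv_sample_pct = 8, seed = 11)
  rep1 <- analyze_replicate(x)
  expect_false(rep1$qc_pass)
  expect_gt(rep1$cv_sample, 5)
  expect_lt(abs(rep1$ratio - 0.74) / 0.74, 0.05)
})

test_that("estimates are invariant to a global intensity rescale", {
  x <- simulate_flow_events(n_events = 10000, ratio = 0.74, seed = 8)
  a <- analyze_replicate(x)
  b <- analyze_replicate(as.numeric(x) * 2.7)
  expect_equal(b$ratio, a$ratio, tolerance = 1e-6)
  expect_equal(b$pg_2c, a$pg_2c, tolerance = 1e-6)
  expect_equal(b$size_mb, a$size_mb, tolerance = 1e-6)
})

test_that("genome_size accepts event lists and grouped data frames", {
  x1 <- simulate_flow_events(n_events = 5000, ratio = 0.74, seed = 31)
  x2 <- simulate_flow_events(n_events = 5000, ratio = 0.74, seed = 32)
  gs <- genome_size(events = list(r1 = as.numeric(x1), r2 = as.numeric(x2)))
  expect_equal(gs$aggregate$n, 2L)
  df <- data.frame(sample_id = rep(c("a", "b"), c(5000, 5000)),
                   intensity = c(as.numeric(x1), as.numeric(x2)))
  gs2 <- genome_size(events = df)
  expect_equal(gs2$aggregate$mean_ratio, gs$aggregate$mean_ratio,
               tolerance = 1e-9)
  expect_error(genome_size(), "exactly one")
  expect_error(genome_size(events = x1, peak_means = data.frame(M = 1, N = 1)),
               "exactly one")
})

test_that("genome_size objects print and summarize their estimate", {
  gs <- genome_size(peak_means = urechis_flow_peaks())
  expect_output(print(gs), "2C content : 1.85")
  expect_output(print(gs), "904.77")
  expect_output(print(summary(gs)), "Per-replicate estimates")
})
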