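# Seeded synthetic-data generators: arm-measurement tables with known ground
# truth, and propidium-iodide-style fluorescence event sets.

# lognormal multiplier with unit mean and the requested CV (in percent)
rlnorm_cv <- function(n, cv_pct) {
  if (cv_pct <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + (cv_pct / 100)^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate per-cell chromosome arm measurements
#'
#' Generates the measurement table of `n_cells` metaphase spreads from a true
#' karyotype (one row per homolog pair with true arm lengths `p` and `q`).
#' Each cell emits two chromosomes per pair; every arm is multiplied by
#' independent lognormal measurement noise of the given CV, and all arms of a
#' cell share a lognormal scale factor (SD `cell_scale_sd_pct`) modelling
#' between-spread condensation differences. Chromosome labels are shuffled
#' within each cell, so recovering the pairing is part of the downstream
#' analysis. Telocentric arms (`p = 0`) stay exactly 0.
#'
#' @param truth data frame with true arm lengths per pair, columns
#'   `short_arm_um` (or `p`) and `long_arm_um` (or `q`).
#' @param n_cells number of cells to simulate.
#' @param noise_cv_pct per-arm measurement noise CV, in percent (`>= 0`).
#' @param cell_scale_sd_pct SD of the shared per-cell scale factor, percent.
#' @param seed integer seed; when given, the output is a pure function of
#'   `(truth, parameters, seed)`.
#' @return Data frame with columns `cell_id`, `chromosome_label`,
#'   `short_arm_um`, `long_arm_um`; the generating truth is attached as
#'   attribute `"truth"` (with the true pair index of every row in attribute
#'   `"true_pairs"`).
#' @examples
#' truth <- karyotype(urechis_arms(), input = "pairs")$per_chromosome
#' sim <- simulate_arm_measurements(
#'   data.frame(short_arm_um = truth$mean_p, long_arm_um = truth$mean_q),
#'   n_cells = 5, noise_cv_pct = 2, seed = 1)
#' head(sim)
#' @export
simulate_arm_measurements <- function(truth, n_cells = 5L, noise_cv_pct = 2,
                                      cell_scale_sd_pct = 5, seed = NULL) {
  tr <- as.data.frame(truth)
  if ("p" %in% names(tr) && !"short_arm_um" %in% names(tr)) tr$short_arm_um <- tr$p
  if ("q" %in% names(tr) && !"long_arm_um" %in% names(tr)) tr$long_arm_um <- tr$q
  if (!all(c("short_arm_um", "long_arm_um") %in% names(tr)))
    stop_input("'truth' needs columns short_arm_um/long_arm_um (or p/q)")
  p <- as.numeric(tr$short_arm_um)
  q <- as.numeric(tr$long_arm_um)
  if (anyNA(p) || anyNA(q) || any(q <= 0) || any(p < 0) || any(q < p))
    stop_input("invalid truth: arm lengths must satisfy q > 0 and q >= p >= 0")
  if (noise_cv_pct < 0 || cell_scale_sd_pct < 0)
    stop_input("noise parameters must be non-negative")
  if (!is_count(n_cells) || n_cells < 1)
    stop_input("'n_cells' must be a positive integer")
  if (!is.null(seed)) set.seed(seed)

  n_pairs <- length(p)
  n_chr <- 2L * n_pairs
  rows <- lapply(seq_len(n_cells), function(cell) {
    scale <- rlnorm_cv(1L, cell_scale_sd_pct)
    pp <- rep(p, each = 2L) * rlnorm_cv(n_chr, noise_cv_pct) * scale
    qq <- rep(q, each = 2L) * rlnorm_cv(n_chr, noise_cv_pct) * scale
    pp[rep(p, each = 2L) == 0] <- 0
    shuffle <- sample.int(n_chr)
    data.frame(
      cell_id = sprintf("cell_%d", cell),
      short_arm_um = pp, long_arm_um = qq,
      true_pair = rep(seq_len(n_pairs), each = 2L),
      stringsAsFactors = FALSE
    )[shuffle, , drop = FALSE]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  true_pairs <- out$true_pair
  out$true_pair <- NULL
  out$chromosome_label <- stats::ave(seq_len(nrow(out)), out$cell_id,
                                     FUN = seq_along)
  out <- out[, c("cell_id", "chromosome_label", "short_arm_um", "long_arm_um")]
  attr(out, "truth") <- data.frame(pair_index = seq_len(n_pairs),
                                   short_arm_um = p, long_arm_um = q,
                                   levan_type = levan_classify(ifelse(p == 0, Inf, q / p)))
  attr(out, "true_pairs") <- true_pairs
  out
}

#' Simulate a mixed standard + sample fluorescence event set
#'
#' Draws a propidium-iodide-style DNA histogram as a mixture of: a standard
#' 2C Gaussian peak, a sample 2C Gaussian peak at `ratio` times the standard
#' mean, G2/doublet components at twice each 2C mean (SD scaled by sqrt(2),
#' as for the sum of two independent nuclei), and low-intensity debris from
#' an exponential truncated below the smaller 2C mean. Intensities are
#' clipped at 0 and the event order is shuffled.
#'
#' @param n_events total number of events (`>= 100`).
#' @param standard_mean mean fluorescence of the standard 2C peak (a.u.).
#' @param ratio sample-to-standard 2C mean ratio, `> 0`.
#' @param cv_standard_pct,cv_sample_pct peak CVs in percent, `> 0`.
#' @param debris_fraction,doublet_fraction mixture fractions in `[0, 1)`;
#'   the doublet fraction is split equally between the two populations.
#' @param debris_scale_frac scale of the debris exponential as a fraction of
#'   the sample 2C mean.
#' @param seed integer seed; same config + seed gives identical events.
#' @return Numeric vector of event intensities with the generating
#'   parameters attached as attribute `"truth"`.
#' @examples
#' x <- simulate_flow_events(n_events = 1000, seed = 7)
#' length(x)
#' @export
simulate_flow_events <- function(n_events = 10000L, standard_mean = 500,
                                 ratio = 0.74, cv_standard_pct = 3,
                                 cv_sample_pct = 3, debris_fraction = 0.1,
                                 doublet_fraction = 0.02,
                                 debris_scale_frac = 1 / 3, seed = NULL) {
  if (!is_count(n_events) || n_events < 100)
    stop_input("'n_events' must be an integer >= 100")
  if (standard_mean <= 0 || ratio <= 0)
    stop_input("'standard_mean' and 'ratio' must be positive")
  if (cv_standard_pct <= 0 || cv_sample_pct <= 0)
    stop_input("peak CVs must be positive")
  if (debris_fraction < 0 || debris_fraction >= 1 ||
      doublet_fraction < 0 || doublet_fraction >= 1 ||
      debris_fraction + doublet_fraction >= 1)
    stop_input("mixture fractions must lie in [0, 1) and sum below 1")
  if (!is.null(seed)) set.seed(seed)

  sample_mean <- ratio * standard_mean
  sd_std <- standard_mean * cv_standard_pct / 100
  sd_smp <- sample_mean * cv_sample_pct / 100

  n_debris <- round(n_events * debris_fraction)
  n_doublet <- round(n_events * doublet_fraction)
  n_doub_std <- n_doublet %/% 2L
  n_doub_smp <- n_doublet - n_doub_std
  n_2c <- n_events - n_debris - n_doublet
  n_std <- n_2c %/% 2L
  n_smp <- n_2c - n_std

  lower_2c <- min(standard_mean, sample_mean)
  scale <- debris_scale_frac * lower_2c
  # inverse-CDF draw from Exponential(scale) truncated to [0, lower_2c]
  u <- stats::runif(n_debris)
  debris <- -scale * log(1 - u * (1 - exp(-lower_2c / scale)))

  x <- c(
    stats::rnorm(n_std, standard_mean, sd_std),
    stats::rnorm(n_smp, sample_mean, sd_smp),
    stats::rnorm(n_doub_std, 2 * standard_mean, sqrt(2) * sd_std),
    stats::rnorm(n_doub_smp, 2 * sample_mean, sqrt(2) * sd_smp),
    debris
  )
  x <- pmax(x, 0)
  x <- x[sample.int(length(x))]
  attr(x, "truth") <- list(
    standard_mean = standard_mean, sample_mean = sample_mean, ratio = ratio,
    cv_standard_pct = cv_standard_pct, cv_sample_pct = cv_sample_pct,
    debris_fraction = debris_fraction, doublet_fraction = doublet_fraction,
    n_events = n_events, seed = seed
  )
  x
}
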