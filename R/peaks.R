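# Fluorescence histogram construction and 2C peak detection.

#' Bin fluorescence events into a histogram
#'
#' @param intensities numeric vector of non-negative fluorescence values.
#' @param bins number of equal-width bins (`>= 10`).
#' @param range numeric `c(low, high)`; defaults to `c(0, max(intensities))`.
#'   Events outside the range are dropped.
#' @return List with `counts`, `mids`, `breaks` and `bin_width`; the counts
#'   sum to the number of in-range events.
#' @export
build_histogram <- function(intensities, bins = 1024L, range = NULL) {
  x <- as.numeric(intensities)
  if (length(x) == 0L)
    stop_input("no fluorescence events supplied")
  if (anyNA(x) || any(!is.finite(x)) || any(x < 0))
    stop_input("intensities must be finite and non-negative")
  if (bins < 10L)
    stop_input("'bins' must be at least 10")
  range <- range %||% c(0, max(x))
  if (range[2L] <= range[1L])
    stop_input("invalid histogram range")
  xs <- x[x >= range[1L] & x <= range[2L]]
  breaks <- seq(range[1L], range[2L], length.out = bins + 1L)
  h <- graphics::hist(xs, breaks = breaks, plot = FALSE)
  list(counts = h$counts, mids = h$mids, breaks = breaks,
       bin_width = diff(range) / bins)
}

# Gaussian kernel smoothing of histogram counts (bandwidth in bins),
# zero-padded so the smoothed vector keeps the histogram's length
smooth_counts <- function(counts, bandwidth = 3) {
  if (bandwidth <= 0) return(as.numeric(counts))
  half <- ceiling(4 * bandwidth)
  kern <- stats::dnorm(seq(-half, half), sd = bandwidth)
  kern <- kern / sum(kern)
  padded <- c(numeric(half), counts, numeric(half))
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(half + 1L):(half + length(counts))])
}

# indices of strict local maxima of y (interior points only)
local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  i[y[i] > y[i - 1L] & y[i] > y[i + 1L]]
}

# topographic prominence of each peak index within y
peak_prominence <- function(y, peaks) {
  vapply(peaks, function(p) {
    h <- y[p]
    left <- if (p > 1L) y[1L:(p - 1L)] else numeric(0)
    hi_l <- which(left > h)
    base_l <- if (length(hi_l)) min(left[max(hi_l):length(left)]) else min(c(left, h))
    right <- if (p < length(y)) y[(p + 1L):length(y)] else numeric(0)
    hi_r <- which(right > h)
    base_r <- if (length(hi_r)) min(right[1L:min(hi_r)]) else min(c(right, h))
    h - max(base_l, base_r)
  }, numeric(1))
}

# sigma estimate from the full width at half maximum of the smoothed
# histogram around a peak index; falls back to the smoothing bandwidth when a
# half-maximum crossing is cut off by a neighbouring peak
fwhm_sigma <- function(y, peak, bin_width, bandwidth) {
  half <- y[peak] / 2
  n <- length(y)
  # descend each flank until half maximum, stopping at a valley so that an
  # overlapping neighbour peak is never climbed through
  li <- peak
  while (li > 1L && y[li] > half && y[li - 1L] < y[li]) li <- li - 1L
  left_ok <- y[li] <= half
  ri <- peak
  while (ri < n && y[ri] > half && y[ri + 1L] < y[ri]) ri <- ri + 1L
  right_ok <- y[ri] <= half
  if (left_ok && right_ok) {
    fwhm <- (ri - li) * bin_width
    max(fwhm / 2.3548, bin_width)
  } else if (right_ok) {
    2 * (ri - peak) * bin_width / 2.3548
  } else if (left_ok) {
    2 * (peak - li) * bin_width / 2.3548
  } else {
    2 * bandwidth * bin_width
  }
}

#' Detect 2C peaks in a fluorescence event distribution
#'
#' Reimplements the interactive gating step of DNA flow cytometry as an
#' automatic procedure: the events are binned, the histogram smoothed with a
#' Gaussian kernel, and local maxima above a debris cutoff and a prominence
#' threshold are taken as candidate peaks. A candidate whose mode lies within
#' `doublet_tol` of twice another retained peak's mode and has the smaller
#' area is discarded as a G2/doublet population. Each retained peak's mean
#' fluorescence is the mean of the events inside a narrow window of
#' `mean_window` smoothing bandwidths around the detected mode (robust to
#' debris tails and neighbouring peaks); its CV and event count are computed
#' over a wide window of `cv_window_sigma` FWHM-estimated standard deviations,
#' capped at the midpoint towards any neighbouring peak.
#'
#' @param intensities numeric vector of fluorescence values.
#' @param n_peaks expected number of 2C peaks (2 for a mixed
#'   standard + sample run, 1 for a single population); `NULL` to return all
#'   retained peaks. A mismatch raises an error with a diagnostic.
#' @param bins,range histogram parameters, see [build_histogram()].
#' @param bandwidth Gaussian smoothing bandwidth in bins.
#' @param min_prominence minimum peak prominence as a fraction of the highest
#'   smoothed count.
#' @param debris_cutoff fraction of the histogram range below which maxima
#'   are treated as debris and ignored.
#' @param doublet_tol relative tolerance for the doublet-position test.
#' @param mean_window half-width of the peak-mean window, in smoothing
#'   bandwidths.
#' @param cv_window_sigma half-width of the CV/count window, in estimated
#'   peak standard deviations.
#' @return Data frame of peaks in ascending mean order with columns
#'   `mean_fluorescence`, `cv_pct`, `event_count`, `mode`, `window_low`,
#'   `window_high`; attribute `"overlap"` flags whether any two peak windows
#'   overlap.
#' @examples
#' set.seed(1)
#' x <- simulate_flow_events(n_events = 5000, seed = 1)
#' detect_2c_peaks(x)
#' @export
detect_2c_peaks <- function(intensities, n_peaks = 2L, bins = 1024L,
                            range = NULL, bandwidth = 3,
                            min_prominence = 0.05, debris_cutoff = 0.10,
                            doublet_tol = 0.05, mean_window = 3,
                            cv_window_sigma = 4) {
  x <- as.numeric(intensities)
  h <- build_histogram(x, bins = bins, range = range)
  y <- smooth_counts(h$counts, bandwidth = bandwidth)

  cand <- local_maxima(y)
  cutoff <- h$breaks[1L] + debris_cutoff * (h$breaks[length(h$breaks)] - h$breaks[1L])
  cand <- cand[h$mids[cand] >= cutoff]
  if (length(cand)) {
    prom <- peak_prominence(y, cand)
    cand <- cand[prom >= min_prominence * max(y)]
  }
  if (!length(cand))
    stop_input("no peak detected above the debris cutoff")

  modes <- h$mids[cand]
  # event count near each mode, used to rank candidates in the doublet test
  areas <- vapply(modes, function(m) sum(x >= m * 0.9 & x <= m * 1.1), numeric(1))
  keep <- rep(TRUE, length(cand))
  for (i in seq_along(cand)) {
    for (j in seq_along(cand)) {
      if (i == j || !keep[j]) next
      # a G2/doublet population is a small fraction of its parent peak, so
      # require a clear area deficit: two 2C peaks that happen to sit at a
      # 2:1 ratio (sample at half the standard) must both survive
      if (abs(modes[i] - 2 * modes[j]) <= doublet_tol * 2 * modes[j] &&
          areas[i] < 0.5 * areas[j])
        keep[i] <- FALSE
    }
  }
  cand <- cand[keep]; modes <- modes[keep]

  if (!is.null(n_peaks) && length(cand) != n_peaks)
    stop_input("expected %d 2C peak(s) but found %d (modes at: %s)",
               n_peaks, length(cand),
               paste(formatC(modes, format = "f", digits = 1), collapse = ", "))

  ord <- order(modes)
  cand <- cand[ord]; modes <- modes[ord]

  res <- lapply(seq_along(cand), function(i) {
    mode <- modes[i]
    sigma <- fwhm_sigma(y, cand[i], h$bin_width, bandwidth)
    lo <- mode - cv_window_sigma * sigma
    hi <- mode + cv_window_sigma * sigma
    if (i > 1L) lo <- max(lo, (mode + modes[i - 1L]) / 2)
    if (i < length(modes)) hi <- min(hi, (mode + modes[i + 1L]) / 2)
    lo <- max(lo, h$breaks[1L])
    hi <- min(hi, h$breaks[length(h$breaks)])
    half_narrow <- mean_window * bandwidth * h$bin_width
    xn <- x[x >= mode - half_narrow & x <= mode + half_narrow]
    xw <- x[x >= lo & x <= hi]
    data.frame(mean_fluorescence = mean(xn),
               cv_pct = peak_cv(x, c(lo, hi)),
               event_count = length(xw),
               mode = mode, window_low = lo, window_high = hi)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$mean_fluorescence), , drop = FALSE]
  rownames(out) <- NULL
  overlap <- FALSE
  if (nrow(out) > 1L)
    overlap <- any(out$window_low[-1L] < out$window_high[-nrow(out)])
  attr(out, "overlap") <- overlap
  out
}

#' Coefficient of variation of a gated peak
#'
#' CV (in percent) of the event intensities inside a window,
#' \eqn{100 \cdot SD / mean}. Flow-cytometry practice requires peak CVs below
#' 5\% for a reliable DNA-content estimate; callers flag (rather than drop)
#' estimates that exceed the threshold.
#'
#' @param intensities numeric vector of fluorescence values.
#' @param window numeric `c(low, high)` gate.
#' @return CV in percent.
#' @export
peak_cv <- function(intensities, window) {
  if (length(window) != 2L || window[1L] >= window[2L])
    stop_input("'window' must be c(low, high) with low < high")
  xw <- intensities[intensities >= window[1L] & intensities <= window[2L]]
  if (length(xw) < 2L)
    stop_input("fewer than 2 events in the window [%g, %g]", window[1L], window[2L])
  100 * stats::sd(xw) / mean(xw)
}
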