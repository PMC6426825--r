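# Genome size estimation from flow-cytometry data with an internal standard.

#' Internal reference standard
#'
#' Describes the co-acquired reference cell population of known DNA content.
#' The default is chicken erythrocytes with 2C = 2.5 pg: published tables
#' using this standard back-calculate consistently to 2.5 pg per diploid
#' nucleus (a frequently mis-printed value; the constant is configurable).
#'
#' @param name standard name.
#' @param two_c_pg 2C DNA content of the standard in picograms, `> 0`.
#' @return A list of class `"reference_standard"`.
#' @export
reference_standard <- function(name = "chicken erythrocytes", two_c_pg = 2.5) {
  if (!is.numeric(two_c_pg) || length(two_c_pg) != 1L ||
      !is.finite(two_c_pg) || two_c_pg <= 0)
    stop_input("'two_c_pg' must be a single positive number")
  structure(list(name = name, two_c_pg = two_c_pg),
            class = "reference_standard")
}

#' @export
print.reference_standard <- function(x, ...) {
  cat(sprintf("Reference standard: %s (2C = %g pg)\n", x$name, x$two_c_pg))
  invisible(x)
}

as_standard <- function(standard) {
  if (inherits(standard, "reference_standard")) return(standard)
  if (is.numeric(standard) && length(standard) == 1L)
    return(reference_standard(two_c_pg = standard))
  stop_input("'standard' must be a reference_standard or a 2C value in pg")
}

#' 2C DNA content from the internal-standard ratio
#'
#' The sample's 2C DNA content follows from the ratio of the two 2C peak
#' fluorescence means: \eqn{Y = (N / M) \times X}, where N is the sample peak
#' mean, M the standard peak mean and X the standard's known 2C content.
#'
#' @param N sample 2C peak mean fluorescence (a.u.), `> 0`.
#' @param M standard 2C peak mean fluorescence (a.u.), `> 0`.
#' @param standard a [reference_standard()] or its 2C content in pg.
#' @return 2C DNA content in picograms.
#' @examples
#' estimate_2c_content(10.6, 14.9, 2.5)  # 1.78 pg
#' @export
estimate_2c_content <- function(N, M, standard = reference_standard()) {
  std <- as_standard(standard)
  if (any(!is.finite(N)) || any(N <= 0) || any(!is.finite(M)) || any(M <= 0))
    stop_input("peak means must be positive and finite")
  (N / M) * std$two_c_pg
}

#' Convert 1C DNA content to genome size
#'
#' Uses the standard conversion \eqn{genome\ size\ (bp) = 0.978 \times 10^9
#' \times DNA\ content\ (pg)} applied to the haploid (1C) content.
#'
#' @param pg_1c 1C DNA content in picograms, `> 0`.
#' @param unit `"Mb"` (default) or `"bp"`.
#' @return Genome size in the requested unit.
#' @examples
#' content_to_genome_size(1.0)  # 978 Mb
#' @export
content_to_genome_size <- function(pg_1c, unit = c("Mb", "bp")) {
  unit <- match.arg(unit)
  if (any(!is.finite(pg_1c)) || any(pg_1c <= 0))
    stop_input("'pg_1c' must be positive and finite")
  bp <- 0.978e9 * pg_1c
  if (unit == "bp") bp else bp / 1e6
}

#' Analyze one mixed standard + sample acquisition
#'
#' Detects exactly two 2C peaks in the event intensities, assigns the sample
#' and standard peaks (by default the lower-mean peak is the sample, as for a
#' species smaller than the standard; set `sample_is_lower = FALSE`
#' otherwise) and computes the replicate's DNA content and genome size with
#' per-peak CV quality control. CVs above `cv_threshold` set `qc_pass` to
#' `FALSE` but the estimate is still returned.
#'
#' @param intensities fluorescence events of the mixed run.
#' @param standard a [reference_standard()] or its 2C content in pg.
#' @param sample_is_lower logical; is the sample peak the lower-mean one?
#' @param replicate_id identifier stored in the result row.
#' @param cv_threshold QC limit for peak CVs, in percent.
#' @param ... passed to [detect_2c_peaks()].
#' @return One-row data frame with `replicate`, `M`, `N`, `ratio`, `pg_2c`,
#'   `pg_1c`, `size_mb`, `cv_standard`, `cv_sample`, `qc_pass`, `overlap`.
#' @export
analyze_replicate <- function(intensities, standard = reference_standard(),
                              sample_is_lower = TRUE, replicate_id = 1L,
                              cv_threshold = 5, ...) {
  std <- as_standard(standard)
  peaks <- detect_2c_peaks(intensities, n_peaks = 2L, ...)
  i_sample <- if (sample_is_lower) 1L else 2L
  i_standard <- 3L - i_sample
  N <- peaks$mean_fluorescence[i_sample]
  M <- peaks$mean_fluorescence[i_standard]
  cv_sample <- peaks$cv_pct[i_sample]
  cv_standard <- peaks$cv_pct[i_standard]
  pg_2c <- estimate_2c_content(N, M, std)
  data.frame(
    replicate = replicate_id,
    M = M, N = N, ratio = N / M,
    pg_2c = pg_2c, pg_1c = pg_2c / 2,
    size_mb = content_to_genome_size(pg_2c / 2),
    cv_standard = cv_standard, cv_sample = cv_sample,
    qc_pass = cv_standard <= cv_threshold & cv_sample <= cv_threshold,
    overlap = attr(peaks, "overlap"),
    stringsAsFactors = FALSE
  )
}

#' Aggregate genome-size replicates
#'
#' Arithmetic means and standard errors (sample SD / sqrt(n)) of the ratio,
#' 2C content and genome size across replicates.
#'
#' @param replicates data frame of replicate rows (from [analyze_replicate()]
#'   or assembled from peak means).
#' @return List with `n`, `mean_ratio`, `sem_ratio`, `mean_pg_2c`,
#'   `sem_pg_2c`, `mean_pg_1c`, `mean_size_mb`, `sem_size_mb`, `mean_M`,
#'   `sem_M`, `mean_N`, `sem_N`.
#' @export
aggregate_replicates <- function(replicates) {
  r <- as.data.frame(replicates)
  if (nrow(r) == 0L)
    stop_input("no replicates to aggregate")
  list(
    n = nrow(r),
    mean_M = mean(r$M), sem_M = sem(r$M),
    mean_N = mean(r$N), sem_N = sem(r$N),
    mean_ratio = mean(r$ratio), sem_ratio = sem(r$ratio),
    mean_pg_2c = mean(r$pg_2c), sem_pg_2c = sem(r$pg_2c),
    mean_pg_1c = mean(r$pg_1c),
    mean_size_mb = mean(r$size_mb), sem_size_mb = sem(r$size_mb)
  )
}

#' Estimate genome size by flow cytometry with an internal standard
#'
#' The main genome-size entry point. Input is either raw fluorescence events
#' of one or more mixed standard + sample acquisitions (each replicate is
#' processed with [analyze_replicate()]: peak detection, CV quality control,
#' ratio equation) or a table of already-gated peak means (columns `M` and
#' `N`), the form in which published flow-cytometry tables are printed. Each
#' replicate yields \eqn{2C = (N/M) X} pg and a genome size of
#' \eqn{0.978 \times 10^9 \times (2C/2)} bp; replicates are aggregated as
#' mean +/- SEM.
#'
#' @param events raw events: a numeric vector (one replicate), a list of
#'   numeric vectors, or a data frame with columns `sample_id` and
#'   `intensity`. Exactly one of `events` and `peak_means` must be given.
#' @param peak_means data frame with peak-mean columns `M` (standard) and `N`
#'   (sample), optionally `replicate`.
#' @param standard a [reference_standard()] or its 2C content in pg.
#' @param sample_is_lower logical, see [analyze_replicate()].
#' @param cv_threshold QC limit for peak CVs, in percent.
#' @param ... passed to [detect_2c_peaks()] when `events` is used.
#' @return An object of class `"genome_size"`: a list with `replicates`
#'   (data frame), `aggregate` (see [aggregate_replicates()]), `standard`,
#'   `mode` (`"events"` or `"peak_means"`) and `call`. Raw events, when
#'   supplied, are kept in `$events` for plotting.
#' @examples
#' gs <- genome_size(peak_means = urechis_flow_peaks())
#' gs
#' @seealso [simulate_flow_events()], [urechis_flow_peaks()],
#'   [write_genome_size_report()]
#' @export
genome_size <- function(events = NULL, peak_means = NULL,
                        standard = reference_standard(),
                        sample_is_lower = TRUE, cv_threshold = 5, ...) {
  std <- as_standard(standard)
  if (is.null(events) == is.null(peak_means))
    stop_input("supply exactly one of 'events' and 'peak_means'")

  if (!is.null(peak_means)) {
    pm <- as.data.frame(peak_means)
    if (!all(c("M", "N") %in% names(pm)))
      stop_input("'peak_means' needs columns 'M' and 'N'")
    if (nrow(pm) == 0L)
      stop_input("'peak_means' is empty")
    pg_2c <- estimate_2c_content(pm$N, pm$M, std)
    replicates <- data.frame(
      replicate = pm$replicate %||% seq_len(nrow(pm)),
      M = pm$M, N = pm$N, ratio = pm$N / pm$M,
      pg_2c = pg_2c, pg_1c = pg_2c / 2,
      size_mb = content_to_genome_size(pg_2c / 2),
      cv_standard = NA_real_, cv_sample = NA_real_,
      qc_pass = NA, overlap = NA,
      stringsAsFactors = FALSE
    )
    mode <- "peak_means"
    kept_events <- NULL
  } else {
    if (is.data.frame(events)) {
      if (!all(c("sample_id", "intensity") %in% names(events)))
        stop_input("event data frames need columns 'sample_id' and 'intensity'")
      events <- split(events$intensity, events$sample_id)
    }
    if (is.numeric(events)) events <- list(events)
    if (!length(events))
      stop_input("no event replicates supplied")
    ids <- names(events) %||% seq_along(events)
    replicates <- do.call(rbind, lapply(seq_along(events), function(i)
      analyze_replicate(events[[i]], standard = std,
                        sample_is_lower = sample_is_lower,
                        replicate_id = ids[[i]], cv_threshold = cv_threshold,
                        ...)))
    mode <- "events"
    kept_events <- events
  }

  out <- list(
    replicates = replicates,
    aggregate = aggregate_replicates(replicates),
    standard = std,
    cv_threshold = cv_threshold,
    mode = mode,
    events = kept_events,
    call = match.call()
  )
  class(out) <- "genome_size"
  out
}

#' @export
print.genome_size <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("Genome size estimate (standard: %s, 2C = %g pg)\n",
              x$standard$name, x$standard$two_c_pg))
  cat(sprintf("  replicates : %d (%s input)\n", a$n,
              if (x$mode == "events") "raw event" else "peak-means"))
  cat(sprintf("  N/M ratio  : %.2f ± %.2f\n", a$mean_ratio, a$sem_ratio))
  cat(sprintf("  2C content : %.2f ± %.2f pg   (1C = %.2f pg)\n",
              a$mean_pg_2c, a$sem_pg_2c, a$mean_pg_1c))
  cat(sprintf("  genome size: %.2f ± %.2f Mb\n", a$mean_size_mb, a$sem_size_mb))
  if (x$mode == "events") {
    npass <- sum(x$replicates$qc_pass)
    cat(sprintf("  QC         : %d/%d replicates with both peak CVs <= %g%%\n",
                npass, a$n, x$cv_threshold))
  }
  invisible(x)
}

#' @export
summary.genome_size <- function(object, ...) {
  structure(list(gs = object), class = "summary.genome_size")
}

#' @export
print.summary.genome_size <- function(x, ...) {
  print(x$gs)
  cat("\nPer-replicate estimates:\n")
  r <- x$gs$replicates
  r$ratio <- round(r$ratio, 4)
  r$pg_2c <- round(r$pg_2c, 3)
  r$pg_1c <- round(r$pg_1c, 3)
  r$size_mb <- round(r$size_mb, 2)
  print(r, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.genome_size <- function(x, ...) x$replicates

#' Plot method for genome-size estimates
#'
#' With raw events stored, draws the smoothed fluorescence histogram of the
#' first replicate with the detected peak windows shaded; with peak-means
#' input, draws the per-replicate genome-size estimates and their mean.
#'
#' @param x a `"genome_size"` object.
#' @param replicate which stored event replicate to draw.
#' @param ... further arguments passed to the underlying plot call.
#' @export
plot.genome_size <- function(x, replicate = 1L, ...) {
  if (x$mode == "events") {
    ev <- x$events[[replicate]]
    h <- build_histogram(ev)
    y <- smooth_counts(h$counts)
    graphics::plot(h$mids, y, type = "l", xlab = "fluorescence (a.u.)",
                   ylab = "events (smoothed)",
                   main = "DNA content histogram", ...)
    r <- x$replicates[replicate, ]
    graphics::abline(v = c(r$M, r$N), lty = 2, col = c("grey40", "red3"))
    graphics::legend("topright", lty = 2, col = c("grey40", "red3"),
                     legend = c("standard 2C (M)", "sample 2C (N)"), bty = "n")
  } else {
    r <- x$replicates
    graphics::plot(seq_len(nrow(r)), r$size_mb, pch = 19,
                   xlab = "replicate", ylab = "genome size (Mb)",
                   main = "Per-replicate genome size", ...)
    graphics::abline(h = x$aggregate$mean_size_mb, lty = 2)
  }
  invisible(x)
}
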