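# shared internal helpers

# standard error of the mean; defined as 0 for a single observation so that
# one-cell karyotypes and single flow replicates report SEM = 0, not NA
sem <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  stats::sd(x) / sqrt(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# fixed-format number for SVG output; deterministic across locales
fmt_px <- function(x) formatC(x, format = "f", digits = 2)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# "1.97 ± 0.01" style cell used in report tables
fmt_pm <- function(mean, sem, digits = 2) {
  m <- ifelse(is.finite(mean), formatC(mean, format = "f", digits = digits), "Inf")
  s <- ifelse(is.na(sem), "NA", formatC(sem, format = "f", digits = digits))
  paste0(m, " ± ", s)
}
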