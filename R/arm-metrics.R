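#' Levan centromere-position classes
#'
#' Class labels in order of increasing asymmetry: `m` (metacentric),
#' `sm` (submetacentric), `st` (subtelocentric), `t` (telocentric).
#'
#' @export
levan_types <- c("m", "sm", "st", "t")

# lower bounds of the arm-ratio intervals for m, sm, st, t (half-open on the
# right); telocentrics (infinite AR) fall in the last interval
levan_breaks <- c(1, 1.7, 3, 7)

#' Arm ratio of a chromosome
#'
#' The arm ratio (AR) is the long-arm length divided by the short-arm length,
#' \eqn{q/p}. A telocentric chromosome has no short arm (\eqn{p = 0}) and an
#' infinite arm ratio, represented as `Inf`.
#'
#' Measurements must already be oriented so that the long arm is `q`
#' (\eqn{q \ge p}); [classify_cell()] normalizes flipped measurements before
#' calling this.
#'
#' @param short_arm_um short-arm length p in micrometres; `>= 0`.
#' @param long_arm_um long-arm length q in micrometres; `> 0` and `>= p`.
#' @return Numeric vector of arm ratios (`>= 1`, `Inf` for telocentrics).
#' @examples
#' arm_ratio(1.97, 2.20)  # 1.12 (metacentric)
#' arm_ratio(0, 3.74)     # Inf (telocentric)
#' @seealso [levan_classify()], [centromeric_index()]
#' @export
arm_ratio <- function(short_arm_um, long_arm_um) {
  p <- as.numeric(short_arm_um)
  q <- as.numeric(long_arm_um)
  if (length(p) != length(q))
    stop_input("short and long arm vectors must have the same length")
  if (anyNA(p) || anyNA(q))
    stop_input("invalid measurement: arm lengths must not be missing")
  if (any(q <= 0))
    stop_input("invalid measurement: long arm length must be positive")
  if (any(p < 0))
    stop_input("invalid measurement: short arm length must be non-negative")
  if (any(q < p))
    stop_input("invalid measurement: short arm exceeds long arm (orient arms so that q >= p)")
  ifelse(p == 0, Inf, q / p)
}

#' Centromeric index
#'
#' The centromeric index CI is the short-arm fraction of the chromosome,
#' \eqn{p/(p+q)}; it is 0 for telocentrics and 0.5 for a perfectly
#' metacentric chromosome. Used (with total length) as the centromere-position
#' coordinate when pairing homologs.
#'
#' @inheritParams arm_ratio
#' @return Numeric vector in `[0, 0.5]`.
#' @export
centromeric_index <- function(short_arm_um, long_arm_um) {
  # reuse the arm_ratio validation
  invisible(arm_ratio(short_arm_um, long_arm_um))
  short_arm_um / (short_arm_um + long_arm_um)
}

#' Levan classification of centromere position
#'
#' Assigns each arm ratio to one of the four Levan classes using the
#' conventional intervals, half-open on the right:
#' m \eqn{[1, 1.7)}, sm \eqn{[1.7, 3)}, st \eqn{[3, 7)}, t \eqn{[7, \infty]}.
#' Levan's point categories M (AR exactly 1) and T are folded into m and t,
#' matching common 4-class usage.
#'
#' @param ar numeric vector of arm ratios, each `>= 1` or `Inf`.
#' @return Character vector with values from [levan_types].
#' @examples
#' levan_classify(c(1.12, 2.08, 6.27, Inf))  # "m" "sm" "st" "t"
#' @export
levan_classify <- function(ar) {
  if (!is.numeric(ar) || length(ar) == 0L)
    stop_input("invalid ratio: 'ar' must be a non-empty numeric vector")
  if (anyNA(ar))
    stop_input("invalid ratio: arm ratios must not be missing")
  if (any(ar < 1))
    stop_input("invalid ratio: arm ratio below 1 (orient arms so that q >= p)")
  levan_types[findInterval(ar, levan_breaks)]
}
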