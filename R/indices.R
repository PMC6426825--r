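# Whole-karyotype statistics: fundamental number, asymmetry indices,
# Stebbins classification and the karyotype formula string.

# normalize a type-count input (named vector or list) to an integer vector
# over m, sm, st, t with zeros for absent classes
as_type_counts <- function(type_counts) {
  x <- unlist(type_counts)
  if (is.null(names(x)) || !all(names(x) %in% levan_types))
    stop_input("type counts must be named with a subset of: %s",
               paste(levan_types, collapse = ", "))
  if (any(x < 0) || any(x != round(x)))
    stop_input("type counts must be non-negative integers")
  out <- stats::setNames(integer(length(levan_types)), levan_types)
  out[names(x)] <- as.integer(x)
  out
}

#' Fundamental number (FN)
#'
#' The fundamental number is the total count of chromosome arms in the
#' diploid complement: biarmed chromosomes (m, sm, st) contribute 2 arms
#' each, telocentrics (t) contribute 1.
#'
#' @param type_counts named vector of diploid chromosome counts per Levan
#'   class, e.g. `c(m = 10, sm = 6, st = 6, t = 8)`; absent classes count 0.
#' @return Integer arm count.
#' @examples
#' fundamental_number(c(m = 10, sm = 6, st = 6, t = 8))  # 52
#' @export
fundamental_number <- function(type_counts) {
  tc <- as_type_counts(type_counts)
  unname(2L * (tc[["m"]] + tc[["sm"]] + tc[["st"]]) + tc[["t"]])
}

#' Karyotype asymmetry index (AsK)
#'
#' AsK is the total long-arm length as a percentage of the total chromosome
#' length, \eqn{100 \sum q / \sum (p + q)}. It ranges from 50 (all arms
#' equal, fully symmetric) to 100 (fully telocentric).
#'
#' @inheritParams arm_ratio
#' @return AsK in percent.
#' @examples
#' ask_index(c(1, 0), c(1, 2))  # 75
#' @export
ask_index <- function(short_arm_um, long_arm_um) {
  if (length(short_arm_um) == 0L)
    stop_input("cannot compute AsK of an empty chromosome set")
  invisible(arm_ratio(short_arm_um, long_arm_um))
  100 * sum(long_arm_um) / sum(short_arm_um + long_arm_um)
}

#' Longest-to-shortest chromosome length ratio (L/S)
#'
#' @param total_um total chromosome lengths; at least 2 values.
#' @return `max(total_um) / min(total_um)`.
#' @export
ls_ratio <- function(total_um) {
  if (length(total_um) < 2L)
    stop_input("L/S needs at least two chromosomes")
  if (any(!is.finite(total_um)) || any(total_um <= 0))
    stop_input("total lengths must be positive and finite")
  max(total_um) / min(total_um)
}

#' Percentage of chromosomes with arm ratio above 2:1
#'
#' Infinite arm ratios (telocentrics) count as greater than 2.
#'
#' @param ar vector of arm ratios (`>= 1` or `Inf`).
#' @return Percentage in `[0, 100]`.
#' @export
pct_ar_gt2 <- function(ar) {
  if (length(ar) == 0L)
    stop_input("cannot compute the AR > 2:1 percentage of an empty set")
  if (any(is.na(ar)) || any(ar < 1))
    stop_input("invalid ratio: arm ratios must be >= 1 or Inf")
  100 * mean(ar > 2)
}

#' Stebbins karyotype asymmetry class
#'
#' Two-way classification of karyotype asymmetry: the numeric row comes from
#' the proportion of chromosomes with arm ratio above 2:1 (0% -> 1,
#' (0, 50]% -> 2, (50, 100)% -> 3, 100% -> 4) and the letter column from the
#' longest:shortest length ratio (< 2 -> A, 2--4 -> B, > 4 -> C). Boundary
#' values 2 and 4 fall in column B.
#'
#' @param ls longest-to-shortest length ratio, `>= 1`.
#' @param pct_gt2 percentage of chromosomes with AR > 2, in `[0, 100]`.
#' @return Class string such as `"3B"`.
#' @examples
#' stebbins_classify(2.51, 66.7)  # "3B"
#' @export
stebbins_classify <- function(ls, pct_gt2) {
  if (!is.numeric(ls) || length(ls) != 1L || !is.finite(ls) || ls < 1)
    stop_input("'ls' must be a single finite value >= 1")
  if (!is.numeric(pct_gt2) || length(pct_gt2) != 1L ||
      is.na(pct_gt2) || pct_gt2 < 0 || pct_gt2 > 100)
    stop_input("'pct_gt2' must be a single percentage in [0, 100]")
  row <- if (pct_gt2 == 0) "1" else if (pct_gt2 <= 50) "2"
         else if (pct_gt2 < 100) "3" else "4"
  col <- if (ls < 2) "A" else if (ls <= 4) "B" else "C"
  paste0(row, col)
}

#' Karyotype formula string
#'
#' Canonical formula such as `"2n = 30 (10m + 6sm + 6st + 8t)"`; classes with
#' zero count are omitted and the order is always m, sm, st, t.
#'
#' @inheritParams fundamental_number
#' @return Formula string.
#' @examples
#' karyotype_formula(c(m = 20))  # "2n = 20 (20m)"
#' @export
karyotype_formula <- function(type_counts) {
  tc <- as_type_counts(type_counts)
  if (sum(tc) == 0L)
    stop_input("type counts are all zero")
  terms <- paste0(tc[tc > 0L], names(tc)[tc > 0L])
  sprintf("2n = %d (%s)", sum(tc), paste(terms, collapse = " + "))
}
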