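#' Pair homologous chromosomes within a cell
#'
#' Homologs are assigned by similarity in length and centromere position: the
#' set of chromosomes is split into pairs by an exact minimum-weight perfect
#' matching under the pairwise distance
#' \deqn{d(a, b) = w_{len} |T_a - T_b| / \bar{T} + w_{cen} |CI_a - CI_b|}
#' where \eqn{T} is total length, \eqn{\bar{T}} the cell's mean total length
#' and CI the centromeric index (0 for telocentrics).
#'
#' The matching is solved optimally by branch and bound (general, not
#' bipartite, matching); ties between equal-cost matchings are broken
#' deterministically by input order.
#'
#' @param classified data frame from [classify_cell()] with an even number of
#'   rows.
#' @param weights numeric vector `c(length = , centromere = )` giving
#'   \eqn{w_{len}} and \eqn{w_{cen}}; both default to 1.
#' @return Data frame with one row per pair: `pair_index`, the two member row
#'   indices (`member_a`, `member_b`) and labels, pair means `mean_p`,
#'   `mean_q`, `mean_total`, the pair `relative_length_pct` (over the haploid
#'   set of pair means), `arm_ratio` (of the pair means) and `levan_type`.
#'   The full matching is attached as attribute `"mate"`.
#' @examples
#' cell <- classify_cell(data.frame(
#'   short_arm_um = c(1.9, 2.0, 0, 0), long_arm_um = c(2.2, 2.3, 3.7, 3.8)))
#' pair_homologs(cell)
#' @export
pair_homologs <- function(classified, weights = c(length = 1, centromere = 1)) {
  cl <- as.data.frame(classified)
  needed <- c("total_um", "centromeric_index", "short_arm_um", "long_arm_um")
  if (!all(needed %in% names(cl)))
    stop_input("'classified' must come from classify_cell()")
  n <- nrow(cl)
  if (n == 0L || n %% 2L != 0L)
    stop_input("cannot pair %d chromosomes: an even count is required", n)
  w_len <- if (!is.null(names(weights))) weights[["length"]] else weights[[1L]]
  w_cen <- if (!is.null(names(weights))) weights[["centromere"]] else weights[[2L]]

  tt <- cl$total_um
  ci <- cl$centromeric_index
  d <- w_len * abs(outer(tt, tt, "-")) / mean(tt) + w_cen * abs(outer(ci, ci, "-"))
  mate <- min_weight_pairing(d)

  first <- which(seq_len(n) < mate)
  a <- first[order(first)]
  b <- mate[a]
  mean_p <- (cl$short_arm_um[a] + cl$short_arm_um[b]) / 2
  mean_q <- (cl$long_arm_um[a] + cl$long_arm_um[b]) / 2
  mean_total <- mean_p + mean_q
  ar <- ifelse(mean_p == 0, Inf, mean_q / mean_p)
  lab <- if ("chromosome_label" %in% names(cl)) as.character(cl$chromosome_label)
         else as.character(seq_len(n))
  pairs <- data.frame(
    pair_index = seq_along(a),
    member_a = a, member_b = b,
    label_a = lab[a], label_b = lab[b],
    mean_p = mean_p, mean_q = mean_q, mean_total = mean_total,
    relative_length_pct = 100 * mean_total / sum(mean_total),
    arm_ratio = ar,
    levan_type = levan_classify(ar),
    stringsAsFactors = FALSE
  )
  attr(pairs, "mate") <- mate
  attr(pairs, "cost") <- sum(d[cbind(a, b)])
  pairs
}

# Exact minimum-weight perfect matching on a symmetric distance matrix.
# Branch and bound: fix the lowest-index free vertex, try partners in
# ascending distance order, prune with cost + half the sum of every remaining
# vertex's cheapest remaining edge. A greedy matching seeds the upper bound.
min_weight_pairing <- function(d) {
  n <- nrow(d)
  if (n == 0L) return(integer(0))
  if (n %% 2L) stop_input("cannot pair an odd number of chromosomes")
  if (n == 2L) return(c(2L, 1L))

  # greedy upper bound: repeatedly match the globally closest free pair
  mate_best <- integer(n)
  cost_best <- 0
  free <- rep(TRUE, n)
  while (any(free)) {
    idx <- which(free)
    sub <- d[idx, idx, drop = FALSE]
    diag(sub) <- Inf
    k <- arrayInd(which.min(sub), dim(sub))
    i <- idx[k[1L]]; j <- idx[k[2L]]
    mate_best[i] <- j; mate_best[j] <- i
    cost_best <- cost_best + d[i, j]
    free[c(i, j)] <- FALSE
  }

  mate <- integer(n)
  best_cost <- cost_best
  best_mate <- mate_best

  lower_bound <- function(avail) {
    if (length(avail) == 0L) return(0)
    sub <- d[avail, avail, drop = FALSE]
    diag(sub) <- Inf
    sum(apply(sub, 1L, min)) / 2
  }

  search <- function(avail, cost) {
    if (length(avail) == 0L) {
      if (cost < best_cost) {
        best_cost <<- cost
        best_mate <<- mate
      }
      return(invisible(NULL))
    }
    i <- avail[1L]
    rest <- avail[-1L]
    for (j in rest[order(d[i, rest])]) {
      nc <- cost + d[i, j]
      if (nc >= best_cost) break  # partners are in ascending order
      remaining <- rest[rest != j]
      if (nc + lower_bound(remaining) >= best_cost) next
      mate[i] <<- j; mate[j] <<- i
      search(remaining, nc)
    }
    invisible(NULL)
  }
  search(seq_len(n), 0)
  best_mate
}
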