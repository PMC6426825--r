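#' Aggregate homolog pairs across metaphase cells
#'
#' Combines the per-cell pair tables of k cells into per-chromosome statistics
#' (mean and SEM of p, q, total length, relative length and arm ratio, with
#' SEM = sample SD / sqrt(k)). Pairs are aligned across cells by rank: within
#' each cell the pairs are sorted by descending centromeric index (which
#' orders the Levan classes m, sm, st, t without a hard class boundary) with
#' ties broken by descending mean total length, and the i-th pair of every
#' cell is averaged.
#'
#' The aggregated Levan class is re-derived from the mean arm ratio. If any
#' cell contributes an infinite arm ratio at a rank (telocentric), the mean AR
#' at that rank is `Inf` and its SEM is `NA`.
#'
#' @param per_cell_pairs list of pair tables from [pair_homologs()], one per
#'   cell, all with the same number of pairs.
#' @return Data frame with one row per chromosome pair: `pair_index`,
#'   `mean_p`, `sem_p`, `mean_q`, `sem_q`, `mean_total`, `sem_total`,
#'   `mean_rl_pct`, `sem_rl`, `mean_ar`, `sem_ar`, `levan_type`, `n_cells`.
#' @export
aggregate_cells <- function(per_cell_pairs) {
  if (!is.list(per_cell_pairs) || length(per_cell_pairs) == 0L)
    stop_input("'per_cell_pairs' must be a non-empty list of pair tables")
  if (is.data.frame(per_cell_pairs))
    per_cell_pairs <- list(per_cell_pairs)
  counts <- vapply(per_cell_pairs, nrow, integer(1))
  if (length(unique(counts)) != 1L)
    stop_input("cells contribute unequal pair counts (%s); cannot aggregate",
               paste(counts, collapse = ", "))
  n_pairs <- counts[1L]
  k <- length(per_cell_pairs)

  # rank pairs by descending centromeric index (a continuous key that orders
  # m -> sm -> st -> t without a hard class boundary), ties by descending
  # length; sorting on the discrete Levan class instead would mis-align cells
  # whenever measurement noise flips a near-boundary pair's class
  aligned <- lapply(per_cell_pairs, function(tab) {
    ci <- tab$mean_p / tab$mean_total
    tab[order(-ci, -tab$mean_total), , drop = FALSE]
  })

  col_mat <- function(col) vapply(aligned, function(tab) tab[[col]], numeric(n_pairs))
  p <- matrix(col_mat("mean_p"), nrow = n_pairs)
  q <- matrix(col_mat("mean_q"), nrow = n_pairs)
  tot <- matrix(col_mat("mean_total"), nrow = n_pairs)
  rl <- matrix(col_mat("relative_length_pct"), nrow = n_pairs)
  ar <- matrix(col_mat("arm_ratio"), nrow = n_pairs)

  row_sem <- function(m) apply(m, 1L, sem)
  mean_ar <- apply(ar, 1L, function(x) if (any(is.infinite(x))) Inf else mean(x))
  sem_ar <- apply(ar, 1L, function(x) if (any(is.infinite(x))) NA_real_ else sem(x))

  out <- data.frame(
    pair_index = seq_len(n_pairs),
    mean_p = rowMeans(p), sem_p = row_sem(p),
    mean_q = rowMeans(q), sem_q = row_sem(q),
    mean_total = rowMeans(tot), sem_total = row_sem(tot),
    mean_rl_pct = rowMeans(rl), sem_rl = row_sem(rl),
    mean_ar = mean_ar, sem_ar = sem_ar,
    stringsAsFactors = FALSE
  )
  out$levan_type <- levan_classify(out$mean_ar)
  out$n_cells <- k
  out
}
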