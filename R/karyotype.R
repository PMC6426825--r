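#' Reconstruct and classify a karyotype from arm measurements
#'
#' The main karyotype-analysis entry point. From a table of per-chromosome
#' arm-length measurements it classifies every chromosome (arm ratio,
#' relative length, Levan class), assigns homologous pairs within each cell,
#' aggregates pairs across cells (mean +/- SEM) and derives the
#' whole-karyotype statistics: diploid number, Levan type counts, fundamental
#' number, karyotype formula, AsK, L/S, the percentage of arm ratios above
#' 2:1 and the Stebbins class.
#'
#' Two input layouts are supported:
#' \describe{
#'   \item{`input = "cells"`}{raw measurements, one row per chromosome of one
#'     or more full 2n metaphase spreads, grouped by `cell_id`. Chromosomes
#'     are paired within each cell and pairs aggregated across cells.}
#'   \item{`input = "pairs"`}{a per-pair summary, one row per homolog pair
#'     (the haploid complement, as published karyotype tables are printed).
#'     Each row represents both homologs; type counts are doubled and all
#'     SEMs are 0. Input row order is preserved.}
#' }
#'
#' Relative lengths are always expressed over the haploid complement (the set
#' of pair means), matching the convention of published karyotype tables.
#'
#' @param data data frame with columns `short_arm_um` and `long_arm_um` plus,
#'   for `input = "cells"`, `cell_id`; an optional `chromosome_label` column
#'   is carried through. A file path to a measurement CSV (see
#'   [read_arm_measurements()]) is also accepted.
#' @param input `"cells"` for raw per-cell spreads, `"pairs"` for a per-pair
#'   summary table.
#' @param weights pairing weights passed to [pair_homologs()].
#' @return An object of class `"karyotype"`: a list with components
#'   `per_chromosome` (data frame of per-pair statistics), `haploid_n`,
#'   `diploid_2n`, `type_counts` (diploid, named m/sm/st/t),
#'   `fundamental_number`, `formula`, `ask_pct`, `ls_ratio`, `pct_ar_gt2`,
#'   `stebbins_class`, `n_cells`, `input` and `call`.
#' @examples
#' k <- karyotype(urechis_arms(), input = "pairs")
#' k
#' k$fundamental_number
#' @seealso [urechis_arms()], [simulate_arm_measurements()],
#'   [build_idiogram()], [write_karyotype_report()]
#' @export
karyotype <- function(data, input = c("cells", "pairs"),
                      weights = c(length = 1, centromere = 1)) {
  input <- match.arg(input)
  if (is.character(data) && length(data) == 1L)
    data <- read_arm_measurements(data)
  data <- as.data.frame(data)

  if (input == "pairs") {
    cl <- classify_cell(data)
    n_pairs <- nrow(cl)
    per_chr <- data.frame(
      pair_index = seq_len(n_pairs),
      label = if ("chromosome_label" %in% names(cl))
        as.character(cl$chromosome_label) else as.character(seq_len(n_pairs)),
      mean_p = cl$short_arm_um, sem_p = 0,
      mean_q = cl$long_arm_um, sem_q = 0,
      mean_total = cl$total_um, sem_total = 0,
      mean_rl_pct = cl$relative_length_pct, sem_rl = 0,
      mean_ar = cl$arm_ratio,
      sem_ar = ifelse(is.finite(cl$arm_ratio), 0, NA_real_),
      levan_type = cl$levan_type,
      stringsAsFactors = FALSE
    )
    n_cells <- 1L
  } else {
    if (!"cell_id" %in% names(data))
      stop_input("'cell_id' column is required for input = \"cells\"")
    cells <- split(data, data$cell_id)
    pair_tables <- lapply(cells, function(cell)
      pair_homologs(classify_cell(cell), weights = weights))
    per_chr <- aggregate_cells(pair_tables)
    per_chr$label <- as.character(per_chr$pair_index)
    n_cells <- length(cells)
  }

  type_counts <- stats::setNames(integer(length(levan_types)), levan_types)
  tab <- table(factor(per_chr$levan_type, levels = levan_types))
  type_counts[names(tab)] <- 2L * as.integer(tab)  # diploid counts

  out <- list(
    per_chromosome = per_chr,
    haploid_n = nrow(per_chr),
    diploid_2n = 2L * nrow(per_chr),
    type_counts = type_counts,
    fundamental_number = fundamental_number(type_counts),
    formula = karyotype_formula(type_counts),
    ask_pct = ask_index(per_chr$mean_p, per_chr$mean_q),
    # L/S over the diploid complement (each pair mean twice): identical to the
    # haploid value for >= 2 pairs and well-defined (1.0) for a single pair
    ls_ratio = ls_ratio(rep(per_chr$mean_total, 2L)),
    pct_ar_gt2 = pct_ar_gt2(per_chr$mean_ar),
    n_cells = n_cells,
    input = input,
    call = match.call()
  )
  out$stebbins_class <- stebbins_classify(out$ls_ratio, out$pct_ar_gt2)
  class(out) <- "karyotype"
  out
}

#' @export
print.karyotype <- function(x, ...) {
  cat("Karyotype:", x$formula, "\n")
  cat(sprintf("  FN = %d   AsK = %.1f%%   L/S = %.2f   %%AR>2:1 = %.1f%%   Stebbins %s\n",
              x$fundamental_number, x$ask_pct, x$ls_ratio, x$pct_ar_gt2,
              x$stebbins_class))
  cat(sprintf("  %d homolog pairs from %d cell(s) (input: %s)\n",
              x$haploid_n, x$n_cells, x$input))
  invisible(x)
}

#' @export
summary.karyotype <- function(object, ...) {
  structure(list(karyotype = object), class = "summary.karyotype")
}

#' @export
print.summary.karyotype <- function(x, ...) {
  k <- x$karyotype
  print(k)
  pc <- k$per_chromosome
  tab <- data.frame(
    Chr = pc$label,
    p = fmt_pm(pc$mean_p, pc$sem_p),
    q = fmt_pm(pc$mean_q, pc$sem_q),
    Total = fmt_pm(pc$mean_total, pc$sem_total),
    RL = fmt_pm(pc$mean_rl_pct, pc$sem_rl),
    AR = fmt_pm(pc$mean_ar, pc$sem_ar),
    Type = pc$levan_type,
    stringsAsFactors = FALSE
  )
  cat("\nPer-chromosome statistics (mean ± SEM, lengths in µm):\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.karyotype <- function(x, ...) x$per_chromosome

#' Plot method: draws the idiogram
#'
#' @param x a `"karyotype"` object.
#' @param ... passed to [plot.idiogram()].
#' @export
plot.karyotype <- function(x, ...) {
  plot(build_idiogram(x), ...)
}
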