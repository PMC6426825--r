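#' Classify the chromosomes of one metaphase cell
#'
#' Takes the arm measurements of a single cell (or a per-pair summary table,
#' i.e. one row per homolog pair) and derives, per chromosome: total length,
#' relative length, arm ratio, centromeric index and Levan class.
#'
#' Relative length (RL) is the chromosome's total length as a percentage of
#' the summed length of the rows supplied, so RL sums to 100 over a full 2n
#' spread as well as over a haploid per-pair table.
#'
#' Rows whose short arm exceeds the long arm are assumed to be mislabelled
#' upstream and are swapped with a warning rather than rejected.
#'
#' @param measurements data frame with columns `short_arm_um` and
#'   `long_arm_um`, optionally `cell_id` (must be constant) and
#'   `chromosome_label`.
#' @return The input data frame with added columns `total_um`,
#'   `relative_length_pct`, `arm_ratio`, `centromeric_index` and `levan_type`.
#' @examples
#' classify_cell(data.frame(short_arm_um = c(1.97, 0),
#'                          long_arm_um  = c(2.20, 3.74)))
#' @export
classify_cell <- function(measurements) {
  m <- as.data.frame(measurements)
  required <- c("short_arm_um", "long_arm_um")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols))
    stop_input("missing measurement column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(m) == 0L)
    stop_input("no measurements supplied")
  if ("cell_id" %in% names(m) && length(unique(m$cell_id)) > 1L)
    stop_input("measurements mix %d cell ids; classify one cell at a time",
               length(unique(m$cell_id)))

  p <- as.numeric(m$short_arm_um)
  q <- as.numeric(m$long_arm_um)
  flipped <- !is.na(p) & !is.na(q) & p > q
  if (any(flipped)) {
    warning(sprintf("%d measurement(s) had short arm > long arm; arms swapped",
                    sum(flipped)), call. = FALSE)
    tmp <- p[flipped]
    p[flipped] <- q[flipped]
    q[flipped] <- tmp
  }
  m$short_arm_um <- p
  m$long_arm_um <- q

  m$total_um <- p + q
  m$arm_ratio <- arm_ratio(p, q)
  m$centromeric_index <- p / m$total_um
  m$relative_length_pct <- 100 * m$total_um / sum(m$total_um)
  m$levan_type <- levan_classify(m$arm_ratio)
  m
}
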