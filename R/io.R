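# CSV readers and report writers.

#' Read a chromosome arm-measurement CSV
#'
#' Expected header: `cell_id,chromosome_label,short_arm_um,long_arm_um`
#' (UTF-8, decimal point). Telocentric short arms may be given as `0`, empty,
#' `-` or a dash and are read as 0. Malformed rows raise an error naming the
#' offending line.
#'
#' @param path file path.
#' @return Data frame with the four columns above, arm lengths numeric.
#' @export
read_arm_measurements <- function(path) {
  if (!file.exists(path))
    stop_input("measurement file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character", encoding = "UTF-8")
  required <- c("cell_id", "chromosome_label", "short_arm_um", "long_arm_um")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop_input("%s: missing column(s): %s", path,
               paste(missing_cols, collapse = ", "))
  if (nrow(d) == 0L)
    stop_input("%s: no measurement rows", path)

  parse_num <- function(raw, column, zero_ok) {
    raw <- trimws(raw)
    dashes <- raw %in% c("", "-", "–", "—", "NA")
    val <- suppressWarnings(as.numeric(raw))
    if (zero_ok) val[dashes] <- 0
    bad <- which(is.na(val))
    if (length(bad))
      stop_input("%s: line %d: '%s' is not a valid %s", path,
                 bad[1L] + 1L, raw[bad[1L]], column)
    val
  }
  d$short_arm_um <- parse_num(d$short_arm_um, "short arm length", zero_ok = TRUE)
  d$long_arm_um <- parse_num(d$long_arm_um, "long arm length", zero_ok = FALSE)
  d
}

#' Read a fluorescence event CSV
#'
#' Expected header: `sample_id,intensity`, one event per row. Events are
#' returned grouped by sample, ready for [genome_size()].
#'
#' @param path file path.
#' @return Named list of numeric intensity vectors, one per `sample_id`.
#' @export
read_flow_events <- function(path) {
  if (!file.exists(path))
    stop_input("event file not found: %s", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "intensity") %in% names(d)))
    stop_input("%s: expected columns 'sample_id' and 'intensity'", path)
  if (nrow(d) == 0L)
    stop_input("%s: no events", path)
  bad <- which(!is.finite(d$intensity) | d$intensity < 0)
  if (length(bad))
    stop_input("%s: line %d: invalid intensity", path, bad[1L] + 1L)
  split(d$intensity, d$sample_id)
}

#' Write the karyotype report
#'
#' Writes a TSV mirroring published karyotype tables (p, q, Total, RL, AR as
#' `mean ± SEM`, plus the Levan type) and a JSON block with the
#' whole-karyotype summary (2n, FN, formula, AsK, L/S, %AR>2:1, Stebbins
#' class, type counts).
#'
#' @param x a `"karyotype"` object.
#' @param tsv,json output paths; either may be `NULL` to skip.
#' @return Invisibly, the list of files written.
#' @export
write_karyotype_report <- function(x, tsv = NULL, json = NULL) {
  stopifnot(inherits(x, "karyotype"))
  written <- character(0)
  if (!is.null(tsv)) {
    pc <- x$per_chromosome
    tab <- data.frame(
      chr = pc$label,
      p_um = fmt_pm(pc$mean_p, pc$sem_p),
      q_um = fmt_pm(pc$mean_q, pc$sem_q),
      total_um = fmt_pm(pc$mean_total, pc$sem_total),
      rl_pct = fmt_pm(pc$mean_rl_pct, pc$sem_rl),
      ar = fmt_pm(pc$mean_ar, pc$sem_ar),
      type = pc$levan_type,
      stringsAsFactors = FALSE
    )
    utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    written <- c(written, tsv)
  }
  if (!is.null(json)) {
    jsonlite::write_json(karyotype_summary_list(x), json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, json)
  }
  invisible(written)
}

karyotype_summary_list <- function(x) {
  list(
    diploid_2n = x$diploid_2n,
    haploid_n = x$haploid_n,
    type_counts = as.list(x$type_counts),
    fundamental_number = x$fundamental_number,
    formula = x$formula,
    ask_pct = round(x$ask_pct, 1),
    ls_ratio = round(x$ls_ratio, 2),
    pct_ar_gt2 = round(x$pct_ar_gt2, 1),
    stebbins_class = x$stebbins_class,
    n_cells = x$n_cells
  )
}

#' Write the genome-size report
#'
#' JSON with a `replicates` array (M, N, ratio, 2C and 1C content, genome
#' size, per-peak CVs, QC flag) and an `aggregate` block of means +/- SEM.
#'
#' @param x a `"genome_size"` object.
#' @param json output path.
#' @return Invisibly, the path written.
#' @export
write_genome_size_report <- function(x, json) {
  stopifnot(inherits(x, "genome_size"))
  payload <- list(
    standard = list(name = x$standard$name, two_c_pg = x$standard$two_c_pg),
    input = x$mode,
    replicates = x$replicates,
    aggregate = x$aggregate
  )
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(json)
}
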