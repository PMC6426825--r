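# Bundled measurement fixtures (published karyotype and flow-cytometry
# tables for the echiuran Urechis unicinctus and comparison taxa).

extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "karyoflow")
  if (path == "")
    stop_input("bundled data file '%s' not found; is karyoflow installed?", file)
  path
}

#' Published chromosome arm measurements of Urechis unicinctus
#'
#' Mean arm lengths of the 15 homolog pairs of the echiuran worm
#' \emph{Urechis unicinctus} (2n = 30), as published: short arm p and long
#' arm q in micrometres, one row per pair (telocentric pairs have p = 0).
#' Use with `karyotype(..., input = "pairs")`.
#'
#' @return Data frame with columns `cell_id`, `chromosome_label`,
#'   `short_arm_um`, `long_arm_um`.
#' @examples
#' karyotype(urechis_arms(), input = "pairs")
#' @export
urechis_arms <- function() {
  read_arm_measurements(extdata_path("urechis_arm_means.csv"))
}

#' Published flow-cytometry peak means for Urechis unicinctus
#'
#' Gated 2C peak mean fluorescences of ten mixed acquisitions of chicken
#' erythrocytes (internal standard, column `M`) and \emph{U. unicinctus}
#' coelomic cells (column `N`), as published.
#'
#' @return Data frame with columns `replicate`, `M`, `N`.
#' @examples
#' genome_size(peak_means = urechis_flow_peaks())
#' @export
urechis_flow_peaks <- function() {
  utils::read.csv(extdata_path("urechis_flow_peaks.csv"))
}

#' Karyotype summaries of echiurans, sipunculids and annelids
#'
#' Published whole-karyotype summaries of ten species (diploid number, Levan
#' type counts, fundamental number, L/S ratio, mean arm ratio, Stebbins
#' class), used for the cross-taxa asymmetry comparison. Values are stored as
#' printed in the source compilation, including its internal inconsistencies
#' (two rows have fundamental numbers or formulas that do not recompute from
#' their own type counts); they are deliberately not corrected.
#'
#' @return Data frame with columns `species`, `category` (echiuran,
#'   sipunculid, polychaete or oligochaete), `two_n`, `n_m`, `n_sm`, `n_st`,
#'   `n_t`, `fn`, `ls_ratio`, `mean_ar`, `stebbins_class`, `source`.
#' @examples
#' asymmetry_scatter(annelid_karyotypes())
#' @export
annelid_karyotypes <- function() {
  utils::read.csv(extdata_path("annelid_karyotypes.csv"))
}
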