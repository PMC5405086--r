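#' Published parameter values for eight reference protein families
#'
#' Literature-tabulated block parameters for eight orthologous protein
#' families spanning a wide divergence-rate range, from ubiquitin
#' (0.1% per 100 Myr, near-frozen) to kappa-casein (33% per 100 Myr,
#' the fastest-diverging of the set).  Included so the algebraic
#' R-from-CD identity ([r_from_cd()]) and the R-versus-divergence-rate
#' correlation ([correlate_with_divergence()]) can be checked against
#' published values without the original sequence sets, which are not
#' redistributable.
#'
#' The ure (mdr, rd_max) pair is the maximally diverse residue and its
#' RD; `N` is a published ratio parameter whose defining formula is not
#' recoverable and which this package therefore does not compute — the
#' column is carried verbatim for completeness only.
#'
#' Note: applying [r_from_cd()] to the kappa-casein row gives ~42, far
#' from its tabulated R of 92, while the other seven rows agree within
#' +/- 1; that row is internally inconsistent as published.
#'
#' @return data.frame with one row per family: `family`,
#'   `divergence_rate` (% per 100 Myr), `R`, `E`, `N` (%), `mdr`,
#'   `rd_max`, `rd_min_residue`, `rd_min`, `dominant`, `d_percent`,
#'   and the five `cd_*` class diversities (%).
#' @export
reference_families <- function() {
  data.frame(
    family = c("Ubiquitin", "G3PDH", "LDH", "Acid-protease",
               "Hemoglobin", "Ribonucleases", "Somatotropin",
               "Kappa-casein"),
    divergence_rate = c(0.1, 2.2, 3.4, 9, 12, 21, 25, 33),
    R = c(42, 53, 55, 62, 63, 67, 76, 92),
    E = c(42, 46, 56, 52, 52, 57, 44, 32),
    N = c(18, 1, 0, 2, 0, 0, 13, 22),
    mdr = c("K", "V", "V", "S", "L", "S", "S", "V"),
    rd_max = c(18.8, 21.2, 20.9, 23.5, 26.7, 23.4, 20.0, 26.4),
    rd_min_residue = c("C", "W", "W", "C", "P", "W", "W", "C"),
    rd_min = c(0.5, 1.4, 1.8, 1.6, 2.2, 3.3, 0.1, 0.6),
    dominant = c("IV", "IV", "IV", "IV", "FL", "TS", "ED", "VA"),
    d_percent = c(5.1, 9.2, 7.6, 4.7, 6.7, 4.1, 5.0, 9.6),
    cd_acidic = c(30.5, 23.3, 18.8, 16.5, 5.61, 15.9, 21.6, 12.7),
    cd_basic = c(34.8, 24, 21.9, 13.5, 16.2, 38, 22.9, 12.9),
    cd_non_polar = c(49.8, 36.2, 44, 57.3, 47.2, 56.4, 55.2, 48.7),
    cd_hydrophobic = c(50.7, 69.8, 69.4, 68.6, 81.5, 58.2, 62.8, 80.6),
    cd_hydrophilic = c(78.6, 64.9, 66.1, 69.6, 56.9, 81.8, 80.4, 48.8),
    stringsAsFactors = FALSE)
}
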