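#' Published 1:1 SPR kinetics of METTL3-METTL14 on GGACU RNA substrates
#'
#' Reported rate constants and derived dissociation constants for the
#' full-length wild-type METTL3-METTL14 heterodimer binding four RNA
#' substrates (a 30-mer bulged stem-loop, its m6A-methylated form, a 14-mer
#' linear oligo, and its methylated form), fitted with the 1:1 Langmuir
#' model. Columns keep the report's display units (`kon_1e5` in
#' 10^5 M^-1 s^-1, `koff_1e2` in 10^-2 s^-1, `kd_nM`, `rmax_RU`).
#'
#' The r6T-m6A row is internally inconsistent: its printed off-rate and
#' dissociation constant cannot both hold under `KD = koff/kon`
#' (`consistent = FALSE`); it is retained for completeness but excluded
#' from consistency checks.
#'
#' @return A data frame, one row per ligand RNA.
#' @export
spr_reference_1to1 <- function() {
  data.frame(
    ligand = c("rNEAT2", "rNEAT2-m6A", "r6T", "r6T-m6A"),
    analyte = "METTL3-METTL14",
    kon_1e5 = c(1.64, 0.755, 0.855, 0.0774),
    koff_1e2 = c(4.22, 2.55, 11.6, 24100),
    kd_nM = c(256, 337, 1360, 3120),
    rmax_RU = c(519, 450, 421, 555),
    consistent = c(TRUE, TRUE, TRUE, FALSE))
}

#' Published two-state SPR kinetics of the arginine-clasp mutants
#'
#' Reported two-state reaction-model rate constants for the METTL3 R471H
#' and METTL14 R298P mutants on the same four RNA substrates. Rates in SI
#' units; the conformational-step forward rate `kon2_s` is first-order
#' (s^-1) — only then does
#' `KD = (koff1/kon1) * koff2/(kon2 + koff2)` reproduce the reported
#' `kd_nM` column.
#'
#' @return A data frame, one row per ligand/mutant pair.
#' @export
spr_reference_two_state <- function() {
  data.frame(
    ligand = rep(c("rNEAT2", "rNEAT2-m6A", "r6T", "r6T-m6A"), each = 2),
    analyte = rep(c("R471H", "R298P"), 4),
    kon1 = c(2.59e4, 2.93e4, 2.73e4, 2.38e4, 4.43e4, 5.38e3, 6.87e6, 6.62e2),
    koff1 = c(2.17e-2, 2.28e-2, 2.22e-2, 2.77e-2, 3.85e-2, 4.00e-2,
              8.99, 3.66e-2),
    kon2_s = c(6.02e-3, 3.68e-3, 5.82e-3, 6.09e-3, 5.06e-3, 2.14e-3,
               6.74e-3, 2.09e-3),
    koff2_s = c(4.54e-4, 3.11e-3, 4.85e-4, 5.23e-3, 7.21e-4, 8.79e-4,
                1.01e-3, 1.48e-3),
    kd_nM = c(58.8, 356, 62.8, 538, 108, 2160, 171, 22900),
    rmax_RU = c(697, 373, 503, 323, 419, 552, 270, 2470))
}

#' Reported RNA capture levels on the SPR chip
#'
#' Streptavidin-captured biotinyl-RNA levels per flow cell, in RU.
#'
#' @return A data frame with `flow_cell`, `ligand`, `captured_RU`.
#' @export
spr_capture_levels <- function() {
  data.frame(flow_cell = 3:6,
             ligand = c("rNEAT2", "rNEAT2-m6A", "r6T", "r6T-m6A"),
             captured_RU = c(66.4, 62.7, 48.9, 51.2))
}

#' One row of the 1:1 reference table as model parameters
#'
#' @param ligand Ligand RNA name in [spr_reference_1to1()].
#' @return A `one_to_one_params` in SI units.
#' @export
reference_1to1_params <- function(ligand) {
  tab <- spr_reference_1to1()
  row <- tab[tab$ligand == ligand, ]
  if (nrow(row) != 1) stop("unknown ligand: ", ligand)
  one_to_one_params(kon = row$kon_1e5 * 1e5, koff = row$koff_1e2 * 1e-2,
                    Rmax = row$rmax_RU)
}

#' One row of the two-state reference table as model parameters
#'
#' @param ligand Ligand RNA name in [spr_reference_two_state()].
#' @param analyte "R471H" or "R298P".
#' @return A `two_state_params` in SI units.
#' @export
reference_two_state_params <- function(ligand, analyte) {
  tab <- spr_reference_two_state()
  row <- tab[tab$ligand == ligand & tab$analyte == analyte, ]
  if (nrow(row) != 1) stop("unknown ligand/analyte: ", ligand, "/", analyte)
  two_state_params(kon1 = row$kon1, koff1 = row$koff1, kon2 = row$kon2_s,
                   koff2 = row$koff2_s, Rmax = row$rmax_RU)
}
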