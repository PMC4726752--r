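#' Extinction coefficients used by the quantification arithmetic
#'
#' The free-FAD coefficient at 450 nm is recorded as 11300 M^-1 cm^-1
#' (equivalently 11.3 mM^-1 cm^-1, the standard literature value); the
#' NADH coefficient at 340 nm is 6220 M^-1 cm^-1 (6.22 mM^-1 cm^-1). All
#' concentrations in this module are molar and path lengths are in cm.
#'
#' @return A tibble with columns `species`, `wavelength_nm`,
#'   `epsilon_M_cm`.
#' @export
extinction_coefficients <- function() {
  tibble::tibble(
    species = c("FAD", "NADH"),
    wavelength_nm = c(450, 340),
    epsilon_M_cm = c(11300, 6220))
}

check_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be positive and finite", call. = FALSE)
  }
  invisible(x)
}

#' Concentration from absorbance (Beer-Lambert)
#'
#' `c = A / (epsilon * l)`. Vectorized over absorbance.
#'
#' @param absorbance Absorbance (dimensionless, >= 0).
#' @param epsilon Extinction coefficient in M^-1 cm^-1.
#' @param path_cm Path length in cm (default 1).
#' @return Molar concentration(s).
#' @export
#' @examples
#' concentration_from_absorbance(0.113, 11300)  # 10 uM of FAD
concentration_from_absorbance <- function(absorbance, epsilon,
                                          path_cm = 1) {
  if (any(absorbance < 0)) stop("absorbance must be >= 0", call. = FALSE)
  check_positive(epsilon, "epsilon")
  check_positive(path_cm, "path length")
  absorbance / (epsilon * path_cm)
}

#' Cofactor occupancy per protein
#'
#' The flavin (or other cofactor) content per protein monomer as the
#' ratio of molar concentrations. Values above 1 are allowed but flagged
#' with a warning (over-stoichiometry usually means a concentration
#' error).
#'
#' @param cofactor_conc,protein_conc Molar concentrations;
#'   `protein_conc > 0`.
#' @return Occupancy fraction(s).
#' @export
#' @examples
#' cofactor_occupancy(8.5e-6, 10e-6)  # 0.85
cofactor_occupancy <- function(cofactor_conc, protein_conc) {
  if (any(cofactor_conc < 0)) {
    stop("cofactor concentration must be >= 0", call. = FALSE)
  }
  check_positive(protein_conc, "protein concentration")
  occ <- cofactor_conc / protein_conc
  if (any(occ > 1)) {
    warning("occupancy above 1 (over-stoichiometric): check concentrations",
            call. = FALSE)
  }
  occ
}

#' NADH oxidation rate and turnover from an absorbance slope
#'
#' Converts the (negative, for consumption) slope of A340 versus time
#' into a molar consumption rate via Beer-Lambert, and into a turnover
#' number by dividing by the enzyme concentration. The sign convention:
#' consumption gives a negative slope; the magnitude is used.
#'
#' @param slope_per_min Absorbance change per minute (<= 0 for
#'   consumption).
#' @param epsilon Extinction coefficient in M^-1 cm^-1 (default 6220,
#'   NADH at 340 nm).
#' @param path_cm Path length in cm (default 1).
#' @param enzyme_conc Molar enzyme concentration.
#' @return A tibble with `rate_M_per_min` and `turnover_per_min`.
#' @export
#' @examples
#' nadh_oxidation_rate(-0.0622, enzyme_conc = 1e-6)
nadh_oxidation_rate <- function(slope_per_min, epsilon = 6220,
                                path_cm = 1, enzyme_conc) {
  if (any(slope_per_min > 0)) {
    stop("positive slope: NADH consumption must give a non-positive ",
         "slope (sign convention)", call. = FALSE)
  }
  check_positive(epsilon, "epsilon")
  check_positive(path_cm, "path length")
  check_positive(enzyme_conc, "enzyme concentration")
  rate <- abs(slope_per_min) / (epsilon * path_cm)
  tibble::tibble(rate_M_per_min = rate,
                 turnover_per_min = rate / enzyme_conc)
}

#' Internal-standard recovery correction
#'
#' Corrects a measured analyte amount for sample loss during extraction
#' using the recovery of a spiked internal standard (e.g. Q4 spiked
#' before extraction calibrating Q6 losses):
#' `recovery = recovered / added`, `corrected = measured / recovery`.
#' This exactly inverts any uniform loss fraction.
#'
#' @param measured_analyte Measured analyte amount (any amount unit).
#' @param standard_added Amount of internal standard spiked (> 0).
#' @param standard_recovered Amount of internal standard recovered
#'   (>= 0; 0 is an error, since no correction is then possible).
#' @return A tibble with `recovery` and `corrected`.
#' @export
#' @examples
#' internal_standard_correction(40, 100, 80)  # recovery 0.8 -> 50
internal_standard_correction <- function(measured_analyte, standard_added,
                                         standard_recovered) {
  check_positive(standard_added, "standard_added")
  if (any(standard_recovered < 0)) {
    stop("standard_recovered must be >= 0", call. = FALSE)
  }
  recovery <- standard_recovered / standard_added
  if (any(recovery == 0)) {
    stop("zero internal-standard recovery: loss correction undefined",
         call. = FALSE)
  }
  tibble::tibble(recovery = recovery,
                 corrected = measured_analyte / recovery)
}
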