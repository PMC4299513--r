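#' Unit-conversion constants
#'
#' The proteome-fraction description and concentration-based metabolic
#' models are related through the proportionality \eqn{\phi_i = \sigma c_i
#' N_{aa}}: total protein mass tracks cell dry mass, and cell density is
#' constant across nutrient conditions, so a mass fraction is a proxy for
#' intracellular concentration. The conversion factor is
#' \eqn{\sigma = 3.8\times 10^{-7}} per µM per amino-acid residue
#' (mean residue mass 110 Da); it is stored to the two significant figures
#' in common use, not re-derived from cell density.
#'
#' @return A list with \code{sigma} (mass fraction per µM per residue) and
#'   \code{residue_mass_Da}.
#' @export
unit_constants <- function() {
  list(sigma = 3.8e-7, residue_mass_Da = 110)
}

#' Convert intracellular concentration to proteome mass fraction
#'
#' \eqn{\phi = \sigma\, c\, N_{aa}}. With \code{N_aa = 1} this converts a
#' free amino-acid concentration to its mass-fraction pool size \code{a}:
#' 1 mM (1000 µM) corresponds to about 3.8e-4.
#'
#' @param c_uM Concentration(s) in µM, \code{>= 0}.
#' @param N_aa Number of amino-acid residues per molecule (>= 1; 1 for a
#'   free amino acid, ~330 for a typical protein).
#' @return Mass fraction(s).
#' @examples
#' mass_fraction_from_concentration(1000, 1)   # 1 mM amino acid
#' @export
mass_fraction_from_concentration <- function(c_uM, N_aa = 1) {
  if (any(c_uM < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (any(N_aa < 1)) stop("N_aa must be >= 1", call. = FALSE)
  unit_constants()$sigma * c_uM * N_aa
}

#' Convert proteome mass fraction to intracellular concentration
#'
#' Inverse of [mass_fraction_from_concentration()]:
#' \eqn{c = \phi / (\sigma N_{aa})}. A mass fraction of 0.1\% for a typical
#' 330-residue protein corresponds to about 8 µM.
#'
#' @param phi Mass fraction(s), \code{>= 0}.
#' @inheritParams mass_fraction_from_concentration
#' @return Concentration(s) in µM.
#' @examples
#' concentration_from_mass_fraction(0.001, 330)
#' @export
concentration_from_mass_fraction <- function(phi, N_aa = 1) {
  if (any(phi < 0)) stop("mass fraction must be >= 0", call. = FALSE)
  if (any(N_aa < 1)) stop("N_aa must be >= 1", call. = FALSE)
  phi / (unit_constants()$sigma * N_aa)
}
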