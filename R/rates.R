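#' Translational efficiency gamma(a)
#'
#' Hill-activation sigmoid for the translational efficiency:
#' \deqn{\gamma(a) = \gamma_0 \, a^h / (K_\gamma^h + a^h),}
#' with \eqn{h} = \code{p$h_gamma}. Translation is attenuated when the free
#' amino-acid pool drops below \code{K_gamma} (tRNA charging becomes
#' limiting) and saturates at \code{gamma0} for abundant amino acids.
#'
#' @param a Amino-acid mass fraction, non-negative (vectorized).
#' @param p A [growth_params()] object.
#' @return Rate(s) in 1/hour, non-decreasing in \code{a}, bounded by
#'   \code{gamma0}.
#' @export
translational_efficiency <- function(a, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(a < 0)) stop("amino-acid level a must be >= 0", call. = FALSE)
  ah <- a^p$h_gamma
  p$gamma0 * ah / (p$K_gamma^p$h_gamma + ah)
}

#' Nutritional efficiency nu(a)
#'
#' Hill-inhibition sigmoid for the nutritional efficiency:
#' \deqn{\nu(a) = \nu_0 \, K_\nu^h / (K_\nu^h + a^h),}
#' with \eqn{h} = \code{p$h_nu}. End-product inhibition attenuates the
#' amino-acid supply flux when the pool rises above \code{K_nu}; at low pool
#' sizes supply runs at the medium-determined maximum \code{nu0}.
#'
#' @inheritParams translational_efficiency
#' @return Rate(s) in 1/hour, non-increasing in \code{a}, bounded by
#'   \code{nu0}.
#' @export
nutritional_efficiency <- function(a, p) {
  stopifnot(inherits(p, "growth_params"))
  if (any(a < 0)) stop("amino-acid level a must be >= 0", call. = FALSE)
  Kh <- p$K_nu^p$h_nu
  p$nu0 * Kh / (Kh + a^p$h_nu)
}

check_phiR <- function(phiR, p) {
  if (any(phiR < p$phiR_min - 1e-12) || any(phiR > p$phiR_max + 1e-12))
    stop(sprintf("phiR must lie in [phiR_min, phiR_max] = [%g, %g]",
                 p$phiR_min, p$phiR_max), call. = FALSE)
  invisible(phiR)
}

#' Translation (consumption) flux
#'
#' The rate of protein mass accumulation per unit total protein mass, i.e.
#' the instantaneous growth rate \eqn{\lambda = \gamma(a)(\phi_R -
#' \phi_R^{min})}. Equals the amino-acid consumption flux in scaled units.
#'
#' @inheritParams translational_efficiency
#' @param phiR Ribosomal protein mass fraction, in
#'   \code{[phiR_min, phiR_max]}.
#' @return Growth rate(s) lambda in 1/hour.
#' @export
translation_flux <- function(a, phiR, p) {
  stopifnot(inherits(p, "growth_params"))
  check_phiR(phiR, p)
  translational_efficiency(a, p) * pmax(phiR - p$phiR_min, 0)
}

#' Amino-acid supply flux
#'
#' Supply of the growth-limiting amino acid per unit total protein mass,
#' \eqn{\nu(a)(\phi_R^{max} - \phi_R)}: proportional to the metabolic sector
#' \eqn{\phi_P = \phi_R^{max} - \phi_R} through the proteome partitioning
#' constraint. Expressed in units of growth rate (the \code{beta} scale
#' enters only the pool dynamics, see [ode_rhs()]).
#'
#' @inheritParams translation_flux
#' @return Rate(s) in 1/hour.
#' @export
supply_flux <- function(a, phiR, p) {
  stopifnot(inherits(p, "growth_params"))
  check_phiR(phiR, p)
  nutritional_efficiency(a, p) * (p$phiR_max - phiR)
}

#' Net amino-acid flux residual
#'
#' \code{supply_flux - translation_flux}. For fixed interior \code{phiR} the
#' residual is strictly decreasing in \code{a} (supply is non-increasing,
#' consumption non-decreasing) and vanishes exactly at flux balance, which
#' is the steady-state condition of the model.
#'
#' @inheritParams translation_flux
#' @return Signed rate(s) in 1/hour.
#' @seealso [solve_steady_amino_acid()] which finds its root.
#' @export
flux_residual <- function(a, phiR, p) {
  supply_flux(a, phiR, p) - translation_flux(a, phiR, p)
}
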