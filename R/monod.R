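#' Monod parameters for transport-limited growth
#'
#' When the growth-limiting amino acid is supplied by transport from the
#' medium, the transporter efficacy follows a Michaelis form
#' \eqn{k_a(a_{ex}) = k_{cat}\, a_{ex} / (K_M + a_{ex})} in the external
#' concentration. Folding this into the supply law and eliminating the
#' ribosomal fraction through \eqn{\lambda = \gamma(\phi_R - \phi_R^{min})}
#' at flux balance gives a Monod relation
#' \eqn{\lambda(a_{ex}) = \lambda_\infty a_{ex} / (a_{ex} + K_M^{app})}
#' with
#' \deqn{\lambda_\infty = \frac{\gamma\,\nu\,(\phi_R^{max} -
#'   \phi_R^{min})}{\gamma + \nu}, \qquad
#'   K_M^{app} = K_M\,\frac{\gamma}{\gamma + \nu},}
#' where \eqn{\nu} is the nutritional efficiency at saturating substrate.
#' The apparent Michaelis constant therefore inherits an explicit
#' growth-medium dependence through \eqn{\gamma} and \eqn{\nu}: a cell
#' growing with an efficient supply (\eqn{\nu \gg \gamma}) half-saturates
#' at external concentrations well below the transporter's own \eqn{K_M}.
#'
#' @param p A [growth_params()] object; \code{gamma0} and the allocation
#'   bounds enter the plateau-limit expressions.
#' @param K_M Michaelis constant of the transporter (external concentration
#'   units, e.g. µM).
#' @param nu_sat Nutritional efficiency at saturating external substrate
#'   (1/hour); defaults to \code{p$nu0}.
#' @param k_cat Optional transporter turnover rate, stored for reference.
#' @return An object of class \code{"monod_params"} with fields
#'   \code{lambda_inf}, \code{K_M}, \code{K_M_app}, \code{k_cat},
#'   \code{nu_sat}.
#' @examples
#' m <- monod_params(growth_preset("wide", nu0 = 2.5), K_M = 10)
#' m
#' @export
monod_params <- function(p, K_M, nu_sat = p$nu0, k_cat = NULL) {
  stopifnot(inherits(p, "growth_params"), K_M > 0, nu_sat > 0)
  gamma <- p$gamma0
  out <- list(
    lambda_inf = gamma * nu_sat * (p$phiR_max - p$phiR_min) /
      (gamma + nu_sat),
    K_M = K_M,
    K_M_app = K_M * gamma / (gamma + nu_sat),
    k_cat = k_cat, nu_sat = nu_sat, gamma = gamma)
  class(out) <- "monod_params"
  out
}

#' @export
print.monod_params <- function(x, ...) {
  cat("Monod parameters for transport-limited growth\n")
  cat(sprintf("  lambda_inf = %.5g /h; K_M = %g; K_M_app = %.5g (same units)\n",
              x$lambda_inf, x$K_M, x$K_M_app))
  invisible(x)
}

#' Monod growth rate
#'
#' Saturating dependence of the steady-state growth rate on the external
#' substrate concentration,
#' \eqn{\lambda = \lambda_\infty\, a_{ex} / (a_{ex} + K_M^{app})}.
#'
#' @param a_ex External substrate concentration(s), \code{>= 0} (same units
#'   as \code{K_M}).
#' @param m A [monod_params()] object.
#' @return Growth rate(s) in 1/hour; concave, increasing, with half-maximum
#'   exactly at \code{K_M_app} and limit \code{lambda_inf}.
#' @export
monod_growth_rate <- function(a_ex, m) {
  stopifnot(inherits(m, "monod_params"))
  if (any(a_ex < 0))
    stop("external concentration a_ex must be >= 0", call. = FALSE)
  m$lambda_inf * a_ex / (a_ex + m$K_M_app)
}
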