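#' Steady-state amino-acid pool at fixed allocation
#'
#' Solves the flux-balance condition
#' \eqn{\nu(a)(\phi_R^{max} - \phi_R) = \gamma(a)(\phi_R - \phi_R^{min})}
#' for the steady-state amino-acid mass fraction \eqn{a^*}. The residual is
#' strictly decreasing in \eqn{a}, so the root is unique. Root finding is
#' performed on \eqn{\log a} (the pool spans many decades), with a bracket
#' grown geometrically outward from
#' \code{[K_gamma * 1e-6, K_nu * 1e6]} if needed.
#'
#' @param phiR Ribosomal fraction, strictly between \code{phiR_min} and
#'   \code{phiR_max} (at \code{phiR_max} the supply vanishes identically and
#'   the continuous limit \code{a = 0} is returned; at \code{phiR_min}
#'   consumption vanishes for every pool size, there is no finite root, and
#'   an error is raised).
#' @param p A [growth_params()] object.
#' @param tol Relative tolerance on \code{a} (default \code{1e-12}).
#' @return The steady-state amino-acid mass fraction \code{a_star}.
#' @examples
#' p <- growth_preset("narrow")
#' a <- solve_steady_amino_acid(0.2, p)
#' flux_residual(a, 0.2, p)  # ~ 0
#' @export
solve_steady_amino_acid <- function(phiR, p, tol = 1e-12) {
  stopifnot(inherits(p, "growth_params"), tol > 0)
  if (length(phiR) != 1L) return(vapply(phiR, solve_steady_amino_acid,
                                        numeric(1), p = p, tol = tol))
  check_phiR(phiR, p)
  if (phiR <= p$phiR_min)
    stop("degenerate allocation: at phiR = phiR_min consumption vanishes ",
         "for all a and flux balance has no finite root", call. = FALSE)
  if (phiR >= p$phiR_max) return(0)
  if (p$nu0 == 0) return(0)

  f <- function(u) flux_residual(exp(u), phiR, p)
  lo <- log(p$K_gamma * 1e-6)
  hi <- log(p$K_nu * 1e6)
  ex <- 0L
  while (f(lo) <= 0 && ex < 60L) { lo <- lo - log(10); ex <- ex + 1L }
  while (f(hi) >= 0 && ex < 120L) { hi <- hi + log(10); ex <- ex + 1L }
  if (!(f(lo) > 0 && f(hi) < 0))
    stop("flux-balance residual could not be bracketed: residual(",
         signif(exp(lo), 3), ") = ", signif(f(lo), 3), ", residual(",
         signif(exp(hi), 3), ") = ", signif(f(hi), 3), call. = FALSE)
  r <- stats::uniroot(f, c(lo, hi), tol = min(tol, 1e-13), maxiter = 1000L)
  exp(r$root)
}

#' Flux-balance curve phi_R(a)
#'
#' Closed-form inverse of the flux-balance relation: the ribosomal fraction
#' that balances amino-acid supply and consumption at pool size \code{a},
#' \deqn{\phi_R^{bal}(a) = \frac{\nu(a)\,\phi_R^{max} + \gamma(a)\,
#'   \phi_R^{min}}{\nu(a) + \gamma(a)}.}
#' It decreases monotonically from \code{phiR_max} at \code{a = 0} towards
#' \code{phiR_min} as the pool grows, and its graph is the locus of all
#' steady states available to the regulation.
#'
#' @param a Amino-acid mass fraction (vectorized).
#' @param p A [growth_params()] object.
#' @return Ribosomal fraction(s) in \code{[phiR_min, phiR_max]}.
#' @export
phiR_balance <- function(a, p) {
  stopifnot(inherits(p, "growth_params"))
  g <- translational_efficiency(a, p)
  n <- nutritional_efficiency(a, p)
  tot <- g + n
  out <- ifelse(tot > 0, (n * p$phiR_max + g * p$phiR_min) / tot, p$phiR_max)
  out
}

#' Steady-state growth rate as a function of allocation
#'
#' Evaluates \eqn{\lambda(\phi_R) = \gamma(a^*(\phi_R)) (\phi_R -
#' \phi_R^{min})} at the flux-balanced pool \eqn{a^*}. The curve is
#' continuous, vanishes at both allocation bounds (no active ribosomes at
#' \code{phiR_min}; a starved pool at \code{phiR_max}) and has a unique
#' interior maximum.
#'
#' @param phiR Ribosomal fraction(s) in \code{[phiR_min, phiR_max]}.
#' @inheritParams solve_steady_amino_acid
#' @return Growth rate(s) in 1/hour.
#' @export
growth_rate_at <- function(phiR, p, tol = 1e-12) {
  stopifnot(inherits(p, "growth_params"))
  vapply(phiR, function(f) {
    check_phiR(f, p)
    if (f <= p$phiR_min || f >= p$phiR_max) return(0)
    a <- solve_steady_amino_acid(f, p, tol)
    translation_flux(a, f, p)
  }, numeric(1))
}

#' Plateau-limit optimum in closed form
#'
#' When the two sigmoid thresholds are widely separated
#' (\code{K_gamma << K_nu}) both efficiencies sit at their maxima over a
#' range of pool sizes, and the growth-rate maximum approaches the
#' intersection of the two linear growth laws
#' \eqn{\lambda = \gamma_0(\phi_R - \phi_R^{min})} and
#' \eqn{\lambda = \nu_0(\phi_R^{max} - \phi_R)}:
#' \deqn{\hat\lambda = \frac{\gamma_0 \nu_0 (\phi_R^{max} -
#'   \phi_R^{min})}{\gamma_0 + \nu_0}, \qquad
#'   \hat\phi_R = \frac{\gamma_0 \phi_R^{min} + \nu_0 \phi_R^{max}}
#'   {\gamma_0 + \nu_0}.}
#' \code{lambda_hat} is an upper bound on the attainable maximum for any
#' finite threshold separation.
#'
#' @param p A [growth_params()] object.
#' @return A list with elements \code{phiR_hat} and \code{lambda_hat}.
#' @export
closed_form_optimum <- function(p) {
  stopifnot(inherits(p, "growth_params"))
  dphi <- p$phiR_max - p$phiR_min
  tot <- p$gamma0 + p$nu0
  list(phiR_hat = (p$gamma0 * p$phiR_min + p$nu0 * p$phiR_max) / tot,
       lambda_hat = p$gamma0 * p$nu0 * dphi / tot)
}

#' Optimal ribosomal allocation
#'
#' Maximizes the steady-state growth rate \code{\link{growth_rate_at}} over
#' the admissible ribosomal fraction by golden-section/parabolic search
#' (\code{\link[stats]{optimize}}), with a dense-grid fallback should the
#' scalar search be beaten by a coarse scan (not expected for this
#' unimodal profile). Also reports the closed-form plateau-limit bound and
#' the optimality plateau.
#'
#' @param p A [growth_params()] object.
#' @param tol Absolute tolerance on \code{phiR} for the scalar search.
#' @param rel_tol Relative width of the reported optimality plateau
#'   (default 0.10, i.e. ribosomal fractions within 10\% of the optimum).
#' @return An object of class \code{"allocation_optimum"} with fields
#'   \code{phiR_opt}, \code{lambda_opt}, \code{a_opt}, the closed-form
#'   \code{phiR_hat} and \code{lambda_hat}, and \code{plateau} (see
#'   [plateau_band()]).
#' @examples
#' opt <- optimize_allocation(growth_preset("narrow", nu0 = 2.5))
#' opt
#' @export
optimize_allocation <- function(p, tol = 1e-9, rel_tol = 0.10) {
  stopifnot(inherits(p, "growth_params"))
  if (p$nu0 == 0) {
    out <- list(phiR_opt = p$phiR_min, lambda_opt = 0, a_opt = 0,
                phiR_hat = p$phiR_min, lambda_hat = 0,
                plateau = NULL, rel_tol = rel_tol, degenerate = TRUE,
                params = p)
    class(out) <- "allocation_optimum"
    return(out)
  }
  eps <- 1e-9 * (p$phiR_max - p$phiR_min)
  lo <- p$phiR_min + eps
  hi <- p$phiR_max - eps
  f <- function(phi) growth_rate_at(phi, p)
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
  phiR_opt <- opt$maximum
  lambda_opt <- opt$objective

  # guard against a non-unimodal numerical profile: coarse scan + refine
  grid <- seq(lo, hi, length.out = 41L)
  fg <- vapply(grid, f, numeric(1))
  if (max(fg) > lambda_opt + 1e-10 * max(lambda_opt, 1)) {
    warning("scalar search missed the maximum; refining from a dense grid",
            call. = FALSE)
    i <- which.max(fg)
    opt <- stats::optimize(f, c(grid[max(1L, i - 1L)],
                                grid[min(length(grid), i + 1L)]),
                           maximum = TRUE, tol = tol)
    phiR_opt <- opt$maximum
    lambda_opt <- opt$objective
  }
  cf <- closed_form_optimum(p)
  out <- list(phiR_opt = phiR_opt, lambda_opt = lambda_opt,
              a_opt = solve_steady_amino_acid(phiR_opt, p),
              phiR_hat = cf$phiR_hat, lambda_hat = cf$lambda_hat,
              plateau = plateau_band(p, rel_tol, phiR_opt = phiR_opt),
              rel_tol = rel_tol, degenerate = FALSE, params = p)
  class(out) <- "allocation_optimum"
  out
}

#' @export
print.allocation_optimum <- function(x, ...) {
  cat("Optimal ribosomal allocation\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate: nu0 = 0, no growth possible\n")
    return(invisible(x))
  }
  cat(sprintf("  phiR_opt   = %.6f   lambda_opt = %.6f /h   a_opt = %.4g\n",
              x$phiR_opt, x$lambda_opt, x$a_opt))
  cat(sprintf("  plateau-limit bound: phiR_hat = %.6f, lambda_hat = %.6f /h\n",
              x$phiR_hat, x$lambda_hat))
  if (!is.null(x$plateau))
    cat(sprintf(
      "  %g%% plateau: a in [%.3g, %.3g], phiR in [%.4f, %.4f]\n",
      100 * x$rel_tol, x$plateau$a_lo, x$plateau$a_hi,
      x$plateau$phiR_lo, x$plateau$phiR_hi))
  invisible(x)
}

# invert phiR_balance: pool size at which the balance curve passes `target`
invert_balance <- function(target, p) {
  if (target >= p$phiR_max) return(0)
  f <- function(u) phiR_balance(exp(u), p) - target
  lo <- log(p$K_gamma * 1e-9)
  hi <- log(p$K_nu * 1e9)
  ex <- 0L
  while (f(hi) >= 0 && ex < 60L) { hi <- hi + log(10); ex <- ex + 1L }
  if (f(hi) >= 0) return(Inf)   # target at or below phiR_min
  while (f(lo) <= 0 && ex < 120L) { lo <- lo - log(10); ex <- ex + 1L }
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-13, maxiter = 1000L)$root)
}

#' Optimality plateau
#'
#' The connected range of steady-state pool sizes over which the
#' flux-balance curve \code{\link{phiR_balance}} stays within
#' \code{rel_tol} of the optimal ribosomal fraction. Over this plateau the
#' regulation may place the steady state anywhere and still realize a
#' near-optimal proteome partition; the wider the separation
#' \code{K_nu / K_gamma}, the wider the plateau, which is what makes
#' supply-driven activation robust to the precise shape of the control
#' function.
#'
#' @param p A [growth_params()] object.
#' @param rel_tol Relative deviation from the optimum defining the band
#'   (default 0.10).
#' @param phiR_opt Optional precomputed optimal fraction; computed via
#'   [optimize_allocation()] when missing.
#' @return A list with the pool interval \code{a_lo}, \code{a_hi}, its
#'   \code{log10_width}, and the allocation band \code{phiR_lo},
#'   \code{phiR_hi}.
#' @export
plateau_band <- function(p, rel_tol = 0.10, phiR_opt = NULL) {
  stopifnot(inherits(p, "growth_params"), rel_tol > 0, rel_tol < 1)
  if (is.null(phiR_opt))
    phiR_opt <- optimize_allocation(p, rel_tol = rel_tol)$phiR_opt
  phi_hi <- min(phiR_opt * (1 + rel_tol), p$phiR_max)
  phi_lo <- max(phiR_opt * (1 - rel_tol), p$phiR_min)
  a_lo <- invert_balance(phi_hi, p)   # balance curve decreases in a
  a_hi <- invert_balance(phi_lo, p)
  list(a_lo = a_lo, a_hi = a_hi,
       log10_width = if (a_lo > 0 && is.finite(a_hi))
         log10(a_hi / a_lo) else Inf,
       phiR_lo = phi_lo, phiR_hi = phi_hi)
}
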