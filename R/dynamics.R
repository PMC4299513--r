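#' Right-hand side of the regulation dynamics
#'
#' The two-variable dynamical system for the amino-acid pool \eqn{a} and the
#' ribosomal fraction \eqn{\phi_R} under a control function
#' \eqn{\chi_R(a)}:
#' \deqn{\dot a = \beta\,[\nu(a)(\phi_R^{max} - \phi_R) - \lambda] -
#'   a\lambda, \qquad \dot\phi_R = \lambda\,(\chi_R(a) - \phi_R),}
#' with \eqn{\lambda = \gamma(a)\max(\phi_R - \phi_R^{min}, 0)}. The
#' \eqn{-a\lambda} term is dilution by total protein mass growth; it is
#' retained by default for exactness even though \eqn{a \ll 1} makes it
#' small (set \code{dilution = FALSE} to drop it). The growth rate is
#' clamped to 0 below \code{phiR_min} so transients entering that region
#' remain well defined.
#'
#' @param state Numeric vector \code{c(a, phiR)} with \code{a >= 0} and
#'   \code{phiR} in \code{[0, 1]}.
#' @param p A [growth_params()] object.
#' @param chi A [control_function()].
#' @param dilution Keep the \code{-a*lambda} dilution term (default TRUE).
#' @return Numeric vector \code{c(da, dphiR)} of time derivatives (1/hour).
#' @export
ode_rhs <- function(state, p, chi, dilution = TRUE) {
  stopifnot(inherits(p, "growth_params"), inherits(chi, "control_function"))
  a <- max(state[[1]], 0)
  phiR <- state[[2]]
  lambda <- translational_efficiency(a, p) * max(phiR - p$phiR_min, 0)
  da <- p$beta * (nutritional_efficiency(a, p) * (p$phiR_max - phiR) -
                    lambda)
  if (dilution) da <- da - a * lambda
  if (state[[1]] <= 0) da <- max(da, 0)
  c(da, lambda * (chi(a) - phiR))
}

#' Integrate the regulation dynamics
#'
#' Adaptive, stiff-capable integration (\code{\link[deSolve]{ode}} with
#' \code{lsodar}) of [ode_rhs()] from an initial state, stopping early when
#' the dynamics have relaxed (max-norm of the right-hand side below
#' \code{conv_tol}). Output is reported on a log-spaced time grid, since
#' the pool equilibrates on minutes while the proteome composition relaxes
#' over generations.
#'
#' @param a0,phiR0 Initial amino-acid mass fraction (\code{>= 0}) and
#'   ribosomal fraction (in \code{[0, 1]}).
#' @inheritParams ode_rhs
#' @param t_end Integration horizon in hours (default 500).
#' @param conv_tol Convergence threshold on \code{max(abs(rhs))}
#'   (default 1e-9).
#' @param n_out Number of output points (default 200).
#' @param rtol,atol Integrator tolerances.
#' @return An object of class \code{"growth_trajectory"}: list with
#'   \code{series} (data frame \code{t, a, phiR, lambda}), a
#'   \code{converged} flag and \code{terminal} state.
#' @examples
#' p <- growth_preset("wide", nu0 = 3.3)
#' chi <- control_function("hill", K_chi = 7e-4)
#' tr <- simulate_regulation(1e-5, 0.1, chi, p)
#' tr
#' @export
simulate_regulation <- function(a0, phiR0, chi, p, t_end = 500,
                                conv_tol = 1e-9, n_out = 200L,
                                dilution = TRUE,
                                rtol = 1e-10, atol = 1e-14) {
  stopifnot(inherits(p, "growth_params"), inherits(chi, "control_function"),
            a0 >= 0, phiR0 >= 0, phiR0 <= 1, t_end > 0)
  times <- unique(c(0, 10^seq(-3, log10(t_end), length.out = n_out)))
  rhs <- function(t, y, parms) list(ode_rhs(y, p, chi, dilution))
  rootfun <- function(t, y, parms)
    max(abs(ode_rhs(y, p, chi, dilution))) - conv_tol
  sol <- deSolve::ode(y = c(a = a0, phiR = phiR0), times = times,
                      func = rhs, parms = NULL, method = "lsodar",
                      rootfunc = rootfun, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; last valid state: a = ",
         signif(sol[nrow(sol), "a"], 6), ", phiR = ",
         signif(sol[nrow(sol), "phiR"], 6), call. = FALSE)
  df <- as.data.frame(unclass(sol))
  names(df) <- c("t", "a", "phiR")
  df$a <- pmax(df$a, 0)
  df$lambda <- translational_efficiency(df$a, p) *
    pmax(df$phiR - p$phiR_min, 0)
  term <- df[nrow(df), ]
  converged <- max(abs(ode_rhs(c(term$a, term$phiR), p, chi,
                               dilution))) <= conv_tol * (1 + 1e-6)
  out <- list(series = df, converged = converged,
              terminal = list(a = term$a, phiR = term$phiR,
                              lambda = term$lambda, t = term$t),
              params = p, chi = chi)
  class(out) <- "growth_trajectory"
  out
}

#' @export
print.growth_trajectory <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("Growth-regulation trajectory: %d points over %.4g h, %s\n",
              n, x$series$t[n],
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("  terminal state: a = %.4g, phiR = %.5f, lambda = %.5f /h\n",
              x$terminal$a, x$terminal$phiR, x$terminal$lambda))
  invisible(x)
}

#' @export
plot.growth_trajectory <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$t, s$a, type = "l", log = "y", xlab = "time (h)",
                 ylab = "a (mass fraction)", ...)
  graphics::plot(s$t, s$phiR, type = "l", xlab = "time (h)",
                 ylab = expression(phi[R]), ...)
  graphics::plot(s$t, s$lambda, type = "l", xlab = "time (h)",
                 ylab = expression(lambda ~ (h^-1)), ...)
  invisible(x)
}

#' Fixed point of the regulated system
#'
#' The steady state is the intersection of the flux-balance curve
#' \code{\link{phiR_balance}} with the control function: solve
#' \eqn{\chi_R(a) = \phi_R^{bal}(a)} in \eqn{a}. Because \eqn{\chi_R} is
#' non-decreasing and the balance curve is non-increasing, the intersection
#' is unique when it exists. The returned state carries fluxes and a
#' numerical stability assessment (see [stability()]).
#'
#' When \code{dilution = TRUE} (matching the default dynamics) the pool
#' balance includes the \eqn{-a\lambda} dilution term, which shifts the
#' intersection by a relative amount of order \eqn{a^* \ll 1} compared with
#' the pure flux-balance curve.
#'
#' @inheritParams ode_rhs
#' @param tol Relative tolerance on \code{a}.
#' @return An object of class \code{"steady_state"} with fields
#'   \code{a_star}, \code{phiR_star}, \code{lambda_star}, \code{supply},
#'   \code{consumption}, \code{residual} (net pool change, ~0),
#'   \code{converged}, \code{eigenvalues}, \code{stable}.
#' @examples
#' p <- growth_preset("wide", nu0 = 3.3)
#' find_fixed_point(control_function("hill", K_chi = 7e-4), p)
#' @export
find_fixed_point <- function(chi, p, tol = 1e-12, dilution = TRUE) {
  stopifnot(inherits(p, "growth_params"), inherits(chi, "control_function"))
  # allocation that zeroes the pool dynamics at pool size a
  bal <- function(a) {
    g <- translational_efficiency(a, p) *
      (1 + if (dilution) a / p$beta else 0)
    n <- nutritional_efficiency(a, p)
    tot <- g + n
    ifelse(tot > 0, (n * p$phiR_max + g * p$phiR_min) / tot, p$phiR_max)
  }
  s <- function(u) chi(exp(u)) - bal(exp(u))
  lo <- log(p$K_gamma * 1e-9)
  hi <- log(p$K_nu * 1e9)
  ex <- 0L
  while (s(lo) >= 0 && ex < 30L) { lo <- lo - log(10); ex <- ex + 1L }
  while (s(hi) <= 0 && ex < 60L) { hi <- hi + log(10); ex <- ex + 1L }
  if (s(lo) >= 0)
    stop("no fixed point: control function chi_R(a) lies at or above the ",
         "flux-balance curve even at vanishing pool size", call. = FALSE)
  if (s(hi) <= 0)
    stop("no fixed point: control function chi_R(a) stays below the ",
         "flux-balance curve over the admissible pool range", call. = FALSE)
  r <- stats::uniroot(s, c(lo, hi), tol = min(tol, 1e-13), maxiter = 1000L)
  a_star <- exp(r$root)
  phiR_star <- unname(chi(a_star))
  supply <- supply_flux(a_star, phiR_star, p)
  cons <- translation_flux(a_star, phiR_star, p)
  resid <- p$beta * (supply - cons) -
    if (dilution) a_star * cons else 0
  out <- list(a_star = a_star, phiR_star = phiR_star,
              lambda_star = cons, supply = supply, consumption = cons,
              residual = resid, converged = TRUE,
              eigenvalues = NULL, stable = NA, params = p)
  class(out) <- "steady_state"
  st <- stability(out, chi, p, dilution = dilution)
  out$eigenvalues <- st$eigenvalues
  out$stable <- st$stable
  out
}

#' @export
print.steady_state <- function(x, ...) {
  cat("Steady state of the regulated growth system\n")
  cat(sprintf("  a* = %.6g   phiR* = %.6f   lambda* = %.6f /h\n",
              x$a_star, x$phiR_star, x$lambda_star))
  cat(sprintf("  fluxes: supply %.6f, consumption %.6f (residual %.2e)\n",
              x$supply, x$consumption, x$residual))
  if (!is.null(x$eigenvalues))
    cat(sprintf("  Jacobian eigenvalues: %s; %s\n",
                paste(signif(x$eigenvalues, 4), collapse = ", "),
                if (isTRUE(x$stable)) "stable" else "NOT stable"))
  invisible(x)
}

#' Linear stability of a fixed point
#'
#' Builds the 2x2 Jacobian of [ode_rhs()] at a fixed point by central
#' finite differences (relative step 1e-6) and reports its eigenvalues.
#' The state is stable when both real parts are negative. End-product
#' inhibition of the supply makes the flux-balance intersection attracting
#' for any admissible non-decreasing control function; this routine checks
#' that numerically.
#'
#' @param ss A \code{"steady_state"} from [find_fixed_point()] (or any list
#'   with \code{a_star} and \code{phiR_star} that zeroes the dynamics).
#' @inheritParams ode_rhs
#' @param rel_step Relative finite-difference step (default 1e-6).
#' @return List with \code{jacobian}, \code{eigenvalues} and logical
#'   \code{stable}.
#' @export
stability <- function(ss, chi, p, rel_step = 1e-6, dilution = TRUE) {
  stopifnot(inherits(p, "growth_params"), inherits(chi, "control_function"))
  x0 <- c(ss$a_star, ss$phiR_star)
  f0 <- ode_rhs(x0, p, chi, dilution)
  scale <- c(max(abs(x0[1]), p$K_gamma), 1)
  if (max(abs(f0)) > 1e-6 * max(translational_efficiency(x0[1], p), p$nu0, 1))
    stop("stability() requires a fixed point: |rhs| = ",
         signif(max(abs(f0)), 3), " at the supplied state", call. = FALSE)
  J <- matrix(0, 2, 2)
  for (j in 1:2) {
    hstep <- rel_step * max(abs(x0[j]), rel_step * scale[j], 1e-12)
    xp <- x0; xp[j] <- x0[j] + hstep
    xm <- x0; xm[j] <- max(x0[j] - hstep, 0)
    J[, j] <- (ode_rhs(xp, p, chi, dilution) -
                 ode_rhs(xm, p, chi, dilution)) / (xp[j] - xm[j])
  }
  ev <- eigen(J, only.values = TRUE)$values
  list(jacobian = J, eigenvalues = ev, stable = all(Re(ev) < 0))
}
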