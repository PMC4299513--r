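#' Model parameters for the proteome-allocation growth model
#'
#' Constructs and validates the parameter set of the coarse-grained growth
#' model. The proteome is partitioned into a growth-rate-independent sector,
#' a ribosomal sector \eqn{\phi_R} and a metabolic sector \eqn{\phi_P}, with
#' \eqn{\phi_R + \phi_P = \phi_R^{max}} held fixed. Translation converts the
#' free amino-acid pool (mass fraction \eqn{a}) into protein at rate
#' \eqn{\gamma(a)(\phi_R - \phi_R^{min})}; metabolic proteins supply amino
#' acids at rate \eqn{\nu(a)(\phi_R^{max} - \phi_R)}.
#'
#' @param gamma0 Maximal translational efficiency (1/hour): peptide
#'   elongation capacity per unit ribosomal protein mass, set by the medium
#'   and any translation-targeting antibiotics.
#' @param nu0 Maximal nutritional efficiency (1/hour): amino-acid supply
#'   capacity per unit metabolic protein mass, set by nutrient quality.
#' @param K_gamma Amino-acid mass fraction below which translation is
#'   attenuated (half-saturation of \eqn{\gamma(a)}).
#' @param K_nu Amino-acid mass fraction above which supply is feedback
#'   inhibited (half-inhibition of \eqn{\nu(a)}).
#' @param phiR_min Growth-rate-independent ribosomal offset fraction
#'   (inactive ribosomes and similar); translation flux is proportional to
#'   \eqn{\phi_R - \phi_R^{min}}.
#' @param phiR_max Maximum ribosomal fraction; equivalently the combined
#'   size of the two growth-rate-dependent sectors.
#' @param beta Fraction of translation events consuming the growth-limiting
#'   amino acid. Default 1 (scaled units), so that nutritional efficiencies
#'   quoted per unit growth rate can be used unmodified.
#' @param h_gamma,h_nu Hill exponents of the two sigmoids; defaults 1.
#'
#' @return An object of class \code{"growth_params"}: a validated named list.
#' @seealso [growth_preset()] for ready-made parameter sets,
#'   [translational_efficiency()], [solve_steady_amino_acid()].
#' @examples
#' p <- growth_params(gamma0 = 5.9, nu0 = 2.5, K_gamma = 1e-4, K_nu = 5e-4,
#'                    phiR_min = 0.07, phiR_max = 0.55)
#' p
#' @export
growth_params <- function(gamma0, nu0, K_gamma, K_nu,
                          phiR_min, phiR_max,
                          beta = 1, h_gamma = 1, h_nu = 1) {
  p <- list(gamma0 = as.numeric(gamma0), nu0 = as.numeric(nu0),
            K_gamma = as.numeric(K_gamma), K_nu = as.numeric(K_nu),
            phiR_min = as.numeric(phiR_min), phiR_max = as.numeric(phiR_max),
            beta = as.numeric(beta), h_gamma = as.numeric(h_gamma),
            h_nu = as.numeric(h_nu))
  validate_growth_params(p)
  class(p) <- "growth_params"
  p
}

validate_growth_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("gamma0", "nu0", "K_gamma", "K_nu", "phiR_min", "phiR_max",
              "beta", "h_gamma", "h_nu"))
    if (!num1(p[[f]]))
      stop("parameter '", f, "' must be a single finite numeric value",
           call. = FALSE)
  if (p$gamma0 <= 0) stop("gamma0 must be > 0", call. = FALSE)
  if (p$nu0 < 0) stop("nu0 must be >= 0", call. = FALSE)
  if (p$K_gamma <= 0) stop("K_gamma must be > 0", call. = FALSE)
  if (p$K_nu <= 0) stop("K_nu must be > 0", call. = FALSE)
  if (p$beta <= 0 || p$beta > 1) stop("beta must be in (0, 1]", call. = FALSE)
  if (!(p$phiR_min >= 0 && p$phiR_min < p$phiR_max && p$phiR_max <= 1))
    stop("require 0 <= phiR_min < phiR_max <= 1", call. = FALSE)
  if (p$h_gamma < 1 || p$h_nu < 1)
    stop("Hill exponents h_gamma and h_nu must be >= 1", call. = FALSE)
  invisible(p)
}

#' Preset parameter sets
#'
#' Two standard parameterizations calibrated to E. coli proteome
#' measurements: \code{gamma0 = 5.9}/h, ribosomal-fraction bounds 0.07 and
#' 0.55, and \code{K_gamma = 1e-4}. The \code{"narrow"} preset places the
#' feedback-inhibition threshold close to the translation threshold
#' (\code{K_nu = 5 * K_gamma = 5e-4}), giving a narrow optimality plateau;
#' the \code{"wide"} preset separates them by a factor of 50
#' (\code{K_nu = 5e-3}), the regime in which near-optimal regulation is
#' robust. Nutrient quality is set through \code{nu0}; the reference values
#' 2.5, 3.3 and 5.8/h correspond to poor, good and rich media.
#'
#' @param name \code{"narrow"} or \code{"wide"}.
#' @param nu0 Nutritional efficiency (1/hour), default 2.5.
#' @param ... Overrides passed on to [growth_params()].
#' @return A \code{"growth_params"} object.
#' @examples
#' growth_preset("wide", nu0 = 3.3)
#' @export
growth_preset <- function(name = c("narrow", "wide"), nu0 = 2.5, ...) {
  name <- match.arg(name)
  base <- list(gamma0 = 5.9, nu0 = nu0, K_gamma = 1e-4,
               K_nu = if (name == "narrow") 5e-4 else 5e-3,
               phiR_min = 0.07, phiR_max = 0.55)
  args <- utils::modifyList(base, list(...))
  do.call(growth_params, args)
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Proteome-allocation growth model parameters\n")
  cat(sprintf("  gamma0 (max translational efficiency): %g /h\n", x$gamma0))
  cat(sprintf("  nu0    (max nutritional efficiency):   %g /h\n", x$nu0))
  cat(sprintf("  K_gamma = %g, K_nu = %g (mass fraction), K_nu/K_gamma = %g\n",
              x$K_gamma, x$K_nu, x$K_nu / x$K_gamma))
  cat(sprintf("  phiR in [%g, %g]; beta = %g; Hill exponents (%g, %g)\n",
              x$phiR_min, x$phiR_max, x$beta, x$h_gamma, x$h_nu))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of \code{p} with the named fields replaced and the
#' invariants re-validated.
#'
#' @param p A \code{"growth_params"} object.
#' @param ... Named fields to replace, e.g. \code{nu0 = 5.8}.
#' @return A \code{"growth_params"} object.
#' @export
update_params <- function(p, ...) {
  stopifnot(inherits(p, "growth_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(unclass(p)))
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(growth_params, utils::modifyList(unclass(p), repl))
}
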