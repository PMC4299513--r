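#' Fit a linear growth law to (growth rate, ribosomal fraction) data
#'
#' Ordinary least-squares fit of the linear relation between ribosomal
#' protein fraction and growth rate. Under nutrient-quality modulation the
#' law is \eqn{\phi_R = \phi_R^{min} + \lambda/\gamma} (positive slope
#' \eqn{1/\gamma}); under translation inhibition it is
#' \eqn{\phi_R = \phi_R^{max} - \lambda/\nu} (negative slope
#' \eqn{-1/\nu}). The implied efficiency is recovered from the slope
#' accordingly.
#'
#' @param formula Model formula, default \code{phiR ~ lambda}; the response
#'   is the ribosomal fraction and the single regressor the growth rate.
#' @param data Data frame containing the variables (at least 3 rows).
#' @param law \code{"nutrient"} (positive slope expected, efficiency
#'   \eqn{\gamma = 1/slope}) or \code{"translation"} (negative slope,
#'   \eqn{\nu = -1/slope}).
#' @return An object of class \code{"growth_law_fit"} with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{predict} and
#'   \code{residuals}. Fields: \code{slope} (hours), \code{intercept}
#'   (fraction), \code{r.squared}, \code{efficiency} (1/hour), \code{law}.
#' @examples
#' d <- data.frame(lambda = c(0.5, 1, 1.5), phiR = 0.07 + c(0.5, 1, 1.5) / 5.9)
#' fit_growth_law(phiR ~ lambda, d, law = "nutrient")
#' @export
fit_growth_law <- function(formula = phiR ~ lambda, data,
                           law = c("nutrient", "translation")) {
  law <- match.arg(law)
  stopifnot(inherits(formula, "formula"))
  mf <- stats::model.frame(formula, data)
  if (nrow(mf) < 3L)
    stop("growth-law fitting needs at least 3 points", call. = FALSE)
  x <- stats::model.matrix(formula, mf)[, 2]
  if (stats::sd(x) == 0)
    stop("degenerate sweep: the growth rate values are all identical",
         call. = FALSE)
  fit <- stats::lm(formula, data = mf)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  y <- stats::model.response(mf)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  eff <- switch(law, nutrient = 1 / slope, translation = -1 / slope)
  out <- list(slope = slope, intercept = intercept, r.squared = r2,
              efficiency = eff, law = law, lm = fit, n = nrow(mf))
  class(out) <- "growth_law_fit"
  out
}

#' @export
print.growth_law_fit <- function(x, digits = 6, ...) {
  cat(sprintf("Growth-law fit (%s modulation, n = %d)\n", x$law, x$n))
  cat(sprintf("  phiR = %s + %s * lambda   (R^2 = %s)\n",
              signif(x$intercept, digits), signif(x$slope, digits),
              format(x$r.squared, digits = digits)))
  cat(sprintf("  implied %s efficiency: %s /h; intercept estimates %s\n",
              if (x$law == "nutrient") "translational (gamma)"
              else "nutritional (nu)",
              signif(x$efficiency, digits),
              if (x$law == "nutrient") "phiR_min" else "phiR_max"))
  invisible(x)
}

#' @export
coef.growth_law_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.growth_law_fit <- function(object, ...) {
  s <- summary(object$lm, ...)
  cat(sprintf("Growth-law fit, %s modulation; implied efficiency %.5g /h\n\n",
              object$law, object$efficiency))
  print(s$coefficients)
  cat(sprintf("\nR-squared: %.10g on %d points\n", s$r.squared, object$n))
  invisible(s)
}

#' @export
predict.growth_law_fit <- function(object, newdata, ...) {
  stats::predict(object$lm, newdata = newdata, ...)
}

#' @export
residuals.growth_law_fit <- function(object, ...) {
  stats::residuals(object$lm, ...)
}

default_control <- function(p) {
  control_function("hill", baseline = 0, amplitude = 1,
                   K_chi = sqrt(p$K_gamma * p$K_nu), h = 2)
}

#' Growth-law sweeps over nutrient quality or translational capacity
#'
#' Emulates the two classic experimental protocols on the model and fits
#' the resulting linear law. A \code{"nutrient"} sweep varies the maximal
#' nutritional efficiency \code{nu0} (different media); a
#' \code{"translation"} sweep varies the maximal translational efficiency
#' \code{gamma0} (sub-lethal translation-inhibiting antibiotics) at fixed
#' \code{nu0}. For each condition the steady state is obtained either from
#' the regulated dynamical system (\code{method = "regulated"}, the
#' default: the point is that regulation alone, not an optimizer, produces
#' the laws), from numerical optimization of the allocation
#' (\code{"optimal"}), or from the closed-form plateau-limit optimum
#' (\code{"plateau"}).
#'
#' @param p A [growth_params()] object (base parameter set).
#' @param law \code{"nutrient"} or \code{"translation"}.
#' @param values Grid of \code{nu0} (nutrient) or \code{gamma0}
#'   (translation) values, at least 3 distinct values.
#' @param method Steady-state source, see above.
#' @param chi Control function for \code{method = "regulated"}; defaults to
#'   a Hill response centred at the geometric mean of \code{K_gamma} and
#'   \code{K_nu}.
#' @return An object of class \code{"growth_law_sweep"}: list with
#'   \code{table} (data frame \code{value, lambda, phiR, a}) and
#'   \code{fit}, a [fit_growth_law()] result.
#' @examples
#' p <- growth_preset("wide")
#' sw <- growth_law_sweep(p, "nutrient", c(2.5, 3.3, 5.8), method = "plateau")
#' coef(sw$fit)
#' @export
growth_law_sweep <- function(p, law = c("nutrient", "translation"), values,
                             method = c("regulated", "optimal", "plateau"),
                             chi = NULL) {
  law <- match.arg(law)
  method <- match.arg(method)
  stopifnot(inherits(p, "growth_params"))
  values <- as.numeric(values)
  if (length(unique(values)) < 3L)
    stop("sweep grid needs at least 3 distinct ",
         if (law == "nutrient") "nu0" else "gamma0", " values",
         call. = FALSE)
  if (any(values <= 0)) stop("sweep values must be > 0", call. = FALSE)
  if (is.null(chi) && method == "regulated") chi <- default_control(p)

  rows <- lapply(values, function(v) {
    pi <- if (law == "nutrient") update_params(p, nu0 = v)
          else update_params(p, gamma0 = v)
    if (method == "regulated") {
      ss <- find_fixed_point(chi, pi)
      c(value = v, lambda = ss$lambda_star, phiR = ss$phiR_star,
        a = ss$a_star)
    } else if (method == "optimal") {
      opt <- optimize_allocation(pi)
      c(value = v, lambda = opt$lambda_opt, phiR = opt$phiR_opt,
        a = opt$a_opt)
    } else {
      cf <- closed_form_optimum(pi)
      c(value = v, lambda = cf$lambda_hat, phiR = cf$phiR_hat, a = NA_real_)
    }
  })
  tab <- as.data.frame(do.call(rbind, rows))
  fit <- fit_growth_law(phiR ~ lambda, tab,
                        law = if (law == "nutrient") "nutrient"
                              else "translation")
  out <- list(table = tab, fit = fit, law = law, method = method, params = p)
  class(out) <- "growth_law_sweep"
  out
}

#' @export
print.growth_law_sweep <- function(x, ...) {
  cat(sprintf("Growth-law sweep (%s modulation, %s steady states)\n",
              x$law, x$method))
  print(x$table, row.names = FALSE)
  cat("\n")
  print(x$fit)
  invisible(x)
}

#' @export
as.data.frame.growth_law_sweep <- function(x, ...) x$table
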