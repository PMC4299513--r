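#' Ribosome-synthesis control function chi_R(a)
#'
#' Constructs the regulatory map from the amino-acid pool size to the
#' fraction of active ribosomes allocated to making ribosomal proteins.
#' Supply-driven activation requires a non-decreasing map (in E. coli this
#' is realized through ppGpp: abundant amino acids raise tRNA charging,
#' lower ppGpp and de-repress rRNA synthesis); monotonicity and range are
#' validated on construction by dense sampling. At steady state
#' \eqn{\chi_R(a^*) = \phi_R^*}, so for growth the range should intersect
#' \code{(phiR_min, phiR_max)}.
#'
#' Families:
#' \describe{
#'   \item{\code{hill}}{\eqn{\chi_R(a) = b + A\, a^h / (K_\chi^h + a^h)}.}
#'   \item{\code{piecewise}}{linear ramp from \eqn{b} at \eqn{a = 0} to
#'     \eqn{b + A} at \eqn{a = 2 K_\chi} (half-point at \eqn{K_\chi}).}
#'   \item{\code{constant}}{\eqn{\chi_R = b}: the unregulated contrast, in
#'     which a fixed fraction of ribosomes makes ribosomes irrespective of
#'     the pool.}
#'   \item{\code{table}}{monotone interpolation of user-supplied
#'     \code{(a, chi)} pairs (constant beyond the range).}
#' }
#'
#' @param family One of \code{"hill"}, \code{"piecewise"},
#'   \code{"constant"}, \code{"table"}.
#' @param baseline Allocation \eqn{b} at vanishing pool, in \code{[0, 1]}.
#' @param amplitude Dynamic range \eqn{A} of the allocation
#'   (\code{baseline + amplitude <= 1}). An amplitude of 0 reduces any
#'   family to the constant one.
#' @param K_chi Half-point of the response, in amino-acid mass fraction.
#' @param h Hill exponent (\code{hill} family), >= 1.
#' @param table Data frame or list with components \code{a} and \code{chi}
#'   (\code{table} family); \code{chi} must be non-decreasing in \code{a}.
#' @return A callable object of class \code{"control_function"}:
#'   \code{chi(a)} evaluates the allocation.
#' @examples
#' chi <- control_function("hill", baseline = 0, amplitude = 1,
#'                         K_chi = 7e-4, h = 2)
#' chi(c(1e-5, 7e-4, 1e-1))
#' @export
control_function <- function(family = c("hill", "piecewise", "constant",
                                        "table"),
                             baseline = 0, amplitude = 1,
                             K_chi = NULL, h = 2, table = NULL) {
  family <- match.arg(family)
  stopifnot(baseline >= 0, baseline <= 1)
  if (family == "constant") amplitude <- 0
  if (family != "table") {
    stopifnot(amplitude >= 0)
    if (baseline + amplitude > 1 + 1e-12)
      stop("control function range exceeds 1: baseline + amplitude must be <= 1",
           call. = FALSE)
  }
  if (family %in% c("hill", "piecewise") && amplitude > 0) {
    if (is.null(K_chi) || K_chi <= 0)
      stop("K_chi must be a positive mass fraction", call. = FALSE)
  }
  if (family == "hill" && h < 1) stop("Hill exponent h must be >= 1",
                                      call. = FALSE)
  if (family %in% c("hill", "piecewise") && amplitude == 0)
    family <- "constant"

  fn <- switch(family,
    hill = function(a) baseline + amplitude * a^h / (K_chi^h + a^h),
    piecewise = function(a)
      baseline + amplitude * pmin(a / (2 * K_chi), 1),
    constant = function(a) rep_len(baseline, length(a)),
    table = {
      if (is.null(table) || is.null(table$a) || is.null(table$chi))
        stop("table family needs components 'a' and 'chi'", call. = FALSE)
      ta <- as.numeric(table$a); tc <- as.numeric(table$chi)
      if (is.unsorted(ta, strictly = TRUE))
        stop("table abscissae 'a' must be strictly increasing", call. = FALSE)
      if (any(diff(tc) < 0))
        stop("non-monotone control table: chi must be non-decreasing in a ",
             "(supply-driven activation)", call. = FALSE)
      if (any(tc < 0 | tc > 1))
        stop("control table values must lie in [0, 1]", call. = FALSE)
      function(a) stats::approx(ta, tc, xout = a, rule = 2)$y
    })

  # validate monotonicity and range on a dense log grid
  grid <- c(0, 10^seq(-12, 0, length.out = 400L))
  v <- fn(grid)
  if (any(diff(v) < -1e-12))
    stop("control function must be non-decreasing in a", call. = FALSE)
  if (any(v < -1e-12 | v > 1 + 1e-12))
    stop("control function range must lie within [0, 1]", call. = FALSE)

  structure(fn, class = c("control_function", "function"),
            family = family,
            unregulated = family == "constant",
            params = list(baseline = baseline, amplitude = amplitude,
                          K_chi = K_chi, h = h))
}

#' @export
print.control_function <- function(x, ...) {
  pr <- attr(x, "params")
  cat(sprintf("Ribosome-synthesis control function chi_R(a), family '%s'%s\n",
              attr(x, "family"),
              if (attr(x, "unregulated")) " [unregulated]" else ""))
  if (attr(x, "family") %in% c("hill", "piecewise"))
    cat(sprintf("  baseline %g, amplitude %g, K_chi = %g, h = %g\n",
                pr$baseline, pr$amplitude, pr$K_chi, pr$h))
  if (attr(x, "family") == "constant")
    cat(sprintf("  chi_R = %g for all a\n", pr$baseline))
  invisible(x)
}
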