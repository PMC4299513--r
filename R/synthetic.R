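#' Generate a synthetic noisy growth table
#'
#' Emulates a growth-law measurement campaign: nutrient conditions are
#' drawn at random (uniform \code{nu0} over \code{range} for a nutrient
#' sweep; uniform \code{gamma0} for a translation sweep), the model's
#' steady state is computed for each condition, and seeded Gaussian
#' measurement noise is added to the ribosomal fraction (the quantity
#' measured by RNA/protein ratio assays; growth rates are measured far more
#' precisely, so \code{lambda} is left noise-free by default). By default
#' the steady states come from the plateau-limit law line, so
#' \code{noise_sd = 0} gives points exactly on the line and fits recover
#' the generating parameters exactly.
#'
#' @param p True [growth_params()]; default the \code{"wide"} preset.
#' @param n Number of conditions (>= 3), default 20.
#' @param noise_sd Standard deviation of the Gaussian noise on \code{phiR},
#'   default 0.01 (absolute, on the fraction scale).
#' @param seed Integer seed; the table is reproducible given the seed.
#' @param sweep \code{"nutrient"} or \code{"translation"}.
#' @param range Sampling range for the swept efficiency (1/hour). Defaults:
#'   \code{c(0.5, 10)} for \code{nu0} (spanning poor media to rich broth,
#'   i.e. doubling times of roughly 20 minutes to several hours) and
#'   \code{c(0.3, 1) * gamma0} for antibiotic-reduced \code{gamma0}.
#' @param method Steady-state source as in [growth_law_sweep()]; default
#'   \code{"plateau"}.
#' @return A data frame of class \code{"synthetic_growth_table"} with
#'   columns \code{condition}, \code{value}, \code{lambda}, \code{phiR},
#'   and attributes \code{true_params}, \code{noise_sd}, \code{seed},
#'   \code{sweep}.
#' @examples
#' tab <- generate_growth_table(n = 10, seed = 1)
#' fit_growth_law(phiR ~ lambda, tab, law = "nutrient")
#' @export
generate_growth_table <- function(p = growth_preset("wide"), n = 20L,
                                  noise_sd = 0.01, seed = 42L,
                                  sweep = c("nutrient", "translation"),
                                  range = NULL,
                                  method = c("plateau", "regulated",
                                             "optimal")) {
  sweep <- match.arg(sweep)
  method <- match.arg(method)
  stopifnot(inherits(p, "growth_params"), n >= 3L, noise_sd >= 0)
  if (is.null(range))
    range <- if (sweep == "nutrient") c(0.5, 10)
             else c(0.3, 1) * p$gamma0

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))

  values <- stats::runif(n, range[1], range[2])
  sw <- growth_law_sweep(p, law = sweep, values = values, method = method)
  tab <- sw$table
  tab$phiR <- tab$phiR + stats::rnorm(n, 0, noise_sd)
  out <- data.frame(condition = seq_len(n), value = tab$value,
                    lambda = tab$lambda, phiR = tab$phiR)
  attr(out, "true_params") <- p
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- as.integer(seed)
  attr(out, "sweep") <- sweep
  class(out) <- c("synthetic_growth_table", "data.frame")
  out
}
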