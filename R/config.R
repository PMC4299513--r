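#' Load model parameters and run options from a YAML config file
#'
#' The config is a flat YAML mapping whose keys mirror the
#' [growth_params()] argument names (\code{gamma0}, \code{nu0},
#' \code{K_gamma}, \code{K_nu}, \code{phiR_min}, \code{phiR_max},
#' \code{beta}, \code{h_gamma}, \code{h_nu}), plus an optional
#' \code{preset} (\code{"narrow"} or \code{"wide"}) supplying defaults that
#' explicit keys override, and an optional \code{options} mapping passed
#' through untouched for the caller (tolerances, output paths and the
#' like). Unknown top-level keys are rejected so typos fail loudly, and
#' parameter invariants are re-validated with the failing field named.
#'
#' @param path Path to a readable YAML file.
#' @return A list with elements \code{params} (a \code{"growth_params"}
#'   object) and \code{options} (a list, possibly empty).
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("preset: wide", "nu0: 3.3"), cfg)
#' load_growth_config(cfg)$params
#' @export
load_growth_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  par_keys <- c("gamma0", "nu0", "K_gamma", "K_nu", "phiR_min", "phiR_max",
                "beta", "h_gamma", "h_nu")
  known <- c(par_keys, "preset", "options")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  base <- if (!is.null(raw$preset)) {
    if (!raw$preset %in% c("narrow", "wide"))
      stop("unknown preset '", raw$preset,
           "': available presets are 'narrow' and 'wide'", call. = FALSE)
    unclass(growth_preset(raw$preset))
  } else {
    list(beta = 1, h_gamma = 1, h_nu = 1)
  }
  given <- raw[intersect(names(raw), par_keys)]
  merged <- utils::modifyList(base, given)
  missing <- setdiff(c("gamma0", "nu0", "K_gamma", "K_nu",
                       "phiR_min", "phiR_max"), names(merged))
  if (length(missing))
    stop("config is missing required parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  params <- do.call(growth_params, merged)
  list(params = params,
       options = if (is.null(raw$options)) list() else raw$options)
}
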