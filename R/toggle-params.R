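#' Lumped biophysical parameters of a toggle-switch realisation
#'
#' Bundles the four dimensionless parameters of the reduced toggle-switch
#' model: the expression rate `alpha`, the internal resource-usage weight
#' `beta`, the promoter leakiness `nu`, and the context burden `beta_c`
#' accounting for resource sequestration by co-hosted genes.
#'
#' Typical ranges motivated by plasmid copy numbers and measured resource
#' loads are `alpha` in \[0, 300\] and `beta` in \[0, 40\]; `beta` up to about
#' 10 corresponds to expressing one or two genes, larger values to complex
#' downstream circuitry or decoy sites.
#'
#' @param alpha Nonnegative expression rate (dimensionless).
#' @param beta Nonnegative internal resource-usage weight.
#' @param nu Nonnegative promoter leakiness (basal expression under full
#'   repression, relative to the regulated rate).
#' @param beta_c Nonnegative context burden; defaults to 0 (isolated switch).
#' @return An object of class `toggle_params`.
#' @examples
#' toggle_params(alpha = 10, beta = 2)
#' @export
toggle_params <- function(alpha, beta = 0, nu = 0, beta_c = 0) {
  vals <- c(alpha = alpha, beta = beta, nu = nu, beta_c = beta_c)
  if (!all(is.finite(vals))) {
    stop("all toggle parameters must be finite", call. = FALSE)
  }
  if (any(vals < 0)) {
    stop("toggle parameters must be nonnegative, got ",
         paste(sprintf("%s=%g", names(vals)[vals < 0], vals[vals < 0]),
               collapse = ", "), call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, nu = nu, beta_c = beta_c),
            class = "toggle_params")
}

#' @export
print.toggle_params <- function(x, ...) {
  cat(sprintf("toggle switch parameters: alpha=%g, beta=%g, nu=%g, beta_c=%g\n",
              x$alpha, x$beta, x$nu, x$beta_c))
  if (x$nu == 0 && x$alpha > 0) {
    cat(sprintf("  q = 2(1+beta)/alpha = %g\n", q_statistic(x$alpha, x$beta)))
  }
  invisible(x)
}

as_toggle_params <- function(x) {
  if (inherits(x, "toggle_params")) return(x)
  if (is.list(x) || is.numeric(x)) {
    x <- as.list(x)
    return(toggle_params(alpha = x$alpha,
                         beta = if (is.null(x$beta)) 0 else x$beta,
                         nu = if (is.null(x$nu)) 0 else x$nu,
                         beta_c = if (is.null(x$beta_c)) 0 else x$beta_c))
  }
  stop("cannot interpret input as toggle_params", call. = FALSE)
}

#' Serialise toggle parameters to and from JSON
#'
#' The JSON representation is a flat object with keys `alpha`, `beta`, `nu`
#' and `beta_c`, so parameter sets round-trip losslessly between runs and
#' external tools.
#'
#' @param params A [toggle_params()] object.
#' @param path File path; for `params_from_json`, an existing JSON file or a
#'   JSON string.
#' @return `params_to_json` invisibly returns `path`; `params_from_json`
#'   returns a [toggle_params()] object.
#' @export
params_to_json <- function(params, path) {
  params <- as_toggle_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  as_toggle_params(jsonlite::fromJSON(path))
}

#' Convert the alternative leakiness formulation to the canonical one
#'
#' Promoter leakiness can equivalently be written with the basal and
#' regulated contributions sharing a unit total weight, i.e. production
#' proportional to `nu' + (1-nu')/(1+v^2)`. That primed formulation maps
#' exactly onto the canonical additive one via `alpha = alpha'(1-nu')`,
#' `beta = beta'(1-nu')` and `nu = nu'/(1-nu')`; the two vector fields are
#' identical after conversion.
#'
#' @param alpha_p,beta_p Primed expression rate and resource weight.
#' @param nu_p Primed leakiness, must lie in `[0, 1)`.
#' @param beta_c Context burden, passed through unchanged.
#' @return A [toggle_params()] object in the canonical formulation.
#' @examples
#' convert_leakiness(alpha_p = 2, beta_p = 4, nu_p = 0.5) # alpha=1, beta=2, nu=1
#' @export
convert_leakiness <- function(alpha_p, beta_p, nu_p, beta_c = 0) {
  if (!is.finite(nu_p) || nu_p < 0 || nu_p >= 1) {
    stop("nu_p must lie in [0, 1)", call. = FALSE)
  }
  toggle_params(alpha = alpha_p * (1 - nu_p),
                beta = beta_p * (1 - nu_p),
                nu = nu_p / (1 - nu_p),
                beta_c = beta_c)
}
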