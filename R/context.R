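# Context burden: the exact rescaling that maps a loaded switch onto an
# isolated one, critical burden thresholds, and robustness-vs-load curves.

#' Rescale a loaded switch onto an equivalent isolated one
#'
#' The substitutions `alpha <- alpha / (1 + beta_c)` and
#' `beta <- beta / (1 + beta_c)` transform the dynamics exactly as if the
#' context burden were zero: the vector fields of the original and rescaled
#' parameter sets are identical at every state.  Every stability, landscape
#' and population result for isolated switches therefore transfers to
#' loaded ones.
#'
#' @param params A [toggle_params()] object.
#' @return A [toggle_params()] object with `beta_c = 0`.
#' @examples
#' rescale_for_context(toggle_params(10, 2, beta_c = 1))  # alpha 5, beta 1
#' @export
rescale_for_context <- function(params) {
  params <- as_toggle_params(params)
  s <- 1 + params$beta_c
  toggle_params(params$alpha / s, params$beta / s, params$nu, 0)
}

#' Effective q of a loaded switch at zero leakiness
#'
#' @param alpha,beta,beta_c Parameters (vectorised).
#' @return `2 (1 + beta/(1+beta_c)) / (alpha/(1+beta_c))`, strictly
#'   increasing in `beta_c`: context always pushes towards monostability.
#' @export
q_effective <- function(alpha, beta, beta_c) {
  q_statistic(alpha / (1 + beta_c), beta / (1 + beta_c))
}

#' Critical context burden destroying bistability (nu = 0)
#'
#' The burden at which the effective `q` of the rescaled switch reaches 1:
#' `beta_c' = (1 + beta)(1/q - 1)`.  It grows with `beta`, so high internal
#' resource sequestration protects against loading from the context.
#'
#' @param alpha,beta Parameters of the isolated switch; must be bistable
#'   (`q < 1`).
#' @return The critical burden (vectorised).
#' @examples
#' critical_context_burden(16, 3)  # q = 0.5, threshold 4
#' @export
critical_context_burden <- function(alpha, beta) {
  q <- q_statistic(alpha, beta)
  if (any(q >= 1)) {
    stop("switch is already monostable (q >= 1); no critical burden",
         call. = FALSE)
  }
  (1 + beta) * (1 / q - 1)
}

#' Stability and robustness shift induced by context burden
#'
#' Compares a switch with context burden against the same switch isolated:
#' stability class and (when multistable) barrier heights before and after
#' loading.  The loaded switch is analysed through its exact rescaling.
#'
#' @param params A [toggle_params()] object with `beta_c > 0`.
#' @param dt,tol Barrier-integration controls, see [barrier_height()].
#' @return Object of class `context_shift`: list with `original`,
#'   `effective` (rescaled), `class_isolated`, `class_loaded`,
#'   `barrier_isolated`, `barrier_loaded` (NA when monostable).
#' @export
context_shift <- function(params, dt = 1e-3, tol = 1e-8) {
  params <- as_toggle_params(params)
  isolated <- toggle_params(params$alpha, params$beta, params$nu, 0)
  effective <- rescale_for_context(params)
  eq_iso <- find_equilibria(isolated)
  eq_eff <- find_equilibria(effective)
  bar <- function(p, e) {
    if (!e$stability_class %in% c("bistable", "tristable")) return(NA_real_)
    min(barrier_height(p, equilibria = e, dt = dt, tol = tol)$height)
  }
  structure(list(original = params, effective = effective,
                 class_isolated = eq_iso$stability_class,
                 class_loaded = eq_eff$stability_class,
                 barrier_isolated = bar(isolated, eq_iso),
                 barrier_loaded = bar(effective, eq_eff)),
            class = "context_shift")
}

#' @export
print.context_shift <- function(x, ...) {
  cat(sprintf("context shift (beta_c = %g): %s -> %s; barrier %s -> %s\n",
              x$original$beta_c, x$class_isolated, x$class_loaded,
              signif(x$barrier_isolated, 4), signif(x$barrier_loaded, 4)))
  invisible(x)
}

#' Barrier height versus context burden for matched-q switches
#'
#' For parameter sets sharing the same `q` (hence identical initial
#' robustness ranking) at `beta_c = 0`, computes how the potential barrier
#' decays as the context burden grows.  Burden rescales each set to
#' effective parameters; sets pushed past `q_eff = 1` are recorded with
#' barrier 0.  Optionally evaluates the power-law prediction
#' `psi1 (1/q_eff - 1)^psi2` alongside.
#'
#' @param alpha,beta Vectors of matched parameter sets (equal length); their
#'   `q` values must agree within `q_tol`.
#' @param beta_c Vector of context burdens to scan.
#' @param psi Optional numeric `c(psi1, psi2)` for the closed-form
#'   prediction column.
#' @param q_tol Tolerance for the shared-q precondition.
#' @param dt,t_max,tol Barrier-integration controls.
#' @return Data frame with columns `set`, `alpha`, `beta`, `beta_c`,
#'   `q_eff`, `class`, `barrier`, and `prediction` when `psi` is given.
#' @export
context_robustness_curve <- function(alpha, beta, beta_c, psi = NULL,
                                     q_tol = 1e-8, dt = 1e-3, t_max = 1000,
                                     tol = 1e-8) {
  stopifnot(length(alpha) == length(beta))
  q0 <- q_statistic(alpha, beta)
  if (max(q0) - min(q0) > q_tol) {
    stop("parameter sets must share the same q at beta_c = 0", call. = FALSE)
  }
  grid <- expand.grid(set = seq_along(alpha), beta_c = beta_c,
                      KEEP.OUT.ATTRS = FALSE)
  grid$alpha <- alpha[grid$set]
  grid$beta <- beta[grid$set]
  s <- 1 + grid$beta_c
  a_eff <- grid$alpha / s
  b_eff <- grid$beta / s
  grid$q_eff <- q_statistic(a_eff, b_eff)
  grid$class <- ifelse(grid$q_eff < 1, "bistable", "monostable")
  grid$barrier <- 0
  bi <- which(grid$q_eff < 1)
  if (length(bi)) {
    grid$barrier[bi] <- .barrier_nu0_vec(a_eff[bi], b_eff[bi], dt = dt,
                                         t_max = t_max, tol = tol)
  }
  if (!is.null(psi)) {
    grid$prediction <- ifelse(grid$q_eff < 1,
                              psi[1] * (1 / grid$q_eff - 1)^psi[2], 0)
  }
  grid[c("set", "alpha", "beta", "beta_c", "q_eff", "class", "barrier",
         if (!is.null(psi)) "prediction")]
}
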