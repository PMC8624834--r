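# Reduced toggle-switch vector field with leakiness and shared-resource
# competition.  State (y, z) holds the two repressor levels; repressors bind
# as dimers, hence the squared Hill terms.  All heavy numerical routines go
# through the unchecked vectorised kernels below.

# Hill repression term 1/(1+v^2)
.hill <- function(v) 1 / (1 + v * v)

# Unchecked vectorised right-hand side; y, z and the parameters may be
# vectors of a common length (scalars recycle).
.rhs <- function(y, z, alpha, beta, nu, beta_c) {
  hy <- .hill(y)
  hz <- .hill(z)
  denom <- 1 + beta * (2 * nu + hy + hz) + beta_c
  list(dy = alpha * (nu + hz) / denom - y,
       dz = alpha * (nu + hy) / denom - z)
}

.rhs_norm2 <- function(y, z, alpha, beta, nu, beta_c) {
  f <- .rhs(y, z, alpha, beta, nu, beta_c)
  f$dy * f$dy + f$dz * f$dz
}

.check_state <- function(state) {
  if (is.matrix(state)) {
    if (ncol(state) != 2) stop("state matrix must have two columns (y, z)", call. = FALSE)
  } else {
    if (length(state) != 2) stop("state must be a length-2 vector (y, z)", call. = FALSE)
    state <- matrix(state, ncol = 2)
  }
  if (!all(is.finite(state))) stop("state must be finite", call. = FALSE)
  if (any(state < 0)) stop("state must be nonnegative", call. = FALSE)
  state
}

#' Toggle-switch vector field
#'
#' Evaluates the time derivatives of the two repressor levels under the
#' reduced model: production `alpha (nu + 1/(1+v^2))` for each gene, divided
#' by the shared resource load `1 + beta (2 nu + 1/(1+y^2) + 1/(1+z^2)) +
#' beta_c`, minus first-order dilution/degradation.  The field is symmetric
#' under the exchange `y <-> z`.
#'
#' @param state Numeric vector `c(y, z)` or an `n x 2` matrix of states; both
#'   components must be finite and nonnegative.
#' @param params A [toggle_params()] object (or coercible list).
#' @return For a single state, a named numeric vector `c(dy, dz)`; for a
#'   matrix of states, an `n x 2` matrix.
#' @examples
#' toggle_rhs(c(0, 0), toggle_params(alpha = 1)) # c(1, 1)
#' @export
toggle_rhs <- function(state, params) {
  params <- as_toggle_params(params)
  single <- !is.matrix(state)
  state <- .check_state(state)
  f <- .rhs(state[, 1], state[, 2], params$alpha, params$beta, params$nu,
            params$beta_c)
  if (single) c(dy = f$dy, dz = f$dz) else cbind(dy = f$dy, dz = f$dz)
}

# Analytic Jacobian entries of the vector field, vectorised.
.jacobian <- function(y, z, alpha, beta, nu, beta_c) {
  hy <- .hill(y)
  hz <- .hill(z)
  dhy <- -2 * y * hy * hy          # d/dy 1/(1+y^2)
  dhz <- -2 * z * hz * hz
  denom <- 1 + beta * (2 * nu + hy + hz) + beta_c
  d2 <- denom * denom
  list(
    dfy_dy = -alpha * (nu + hz) * beta * dhy / d2 - 1,
    dfy_dz = alpha * dhz / denom - alpha * (nu + hz) * beta * dhz / d2,
    dfz_dy = alpha * dhy / denom - alpha * (nu + hy) * beta * dhy / d2,
    dfz_dz = -alpha * (nu + hy) * beta * dhz / d2 - 1
  )
}

#' Jacobian of the toggle-switch vector field
#'
#' @param state Numeric vector `c(y, z)`, finite and nonnegative.
#' @param params A [toggle_params()] object.
#' @param method `"analytic"` (hand-derived partial derivatives, default) or
#'   `"numeric"` (central finite differences with relative step 1e-6, kept
#'   as an independent check).
#' @return A 2 x 2 numeric matrix of partial derivatives of `(fy, fz)` with
#'   respect to `(y, z)`.
#' @export
toggle_jacobian <- function(state, params, method = c("analytic", "numeric")) {
  params <- as_toggle_params(params)
  method <- match.arg(method)
  state <- .check_state(state)
  y <- state[1, 1]
  z <- state[1, 2]
  if (method == "analytic") {
    j <- .jacobian(y, z, params$alpha, params$beta, params$nu, params$beta_c)
    matrix(c(j$dfy_dy, j$dfz_dy, j$dfy_dz, j$dfz_dz), 2, 2)
  } else {
    hy <- 1e-6 * max(1, abs(y))
    hz <- 1e-6 * max(1, abs(z))
    a <- params$alpha; b <- params$beta; n <- params$nu; bc <- params$beta_c
    fyp <- .rhs(y + hy, z, a, b, n, bc); fym <- .rhs(y - hy, z, a, b, n, bc)
    fzp <- .rhs(y, z + hz, a, b, n, bc); fzm <- .rhs(y, z - hz, a, b, n, bc)
    matrix(c((fyp$dy - fym$dy) / (2 * hy), (fyp$dz - fym$dz) / (2 * hy),
             (fzp$dy - fzm$dy) / (2 * hz), (fzp$dz - fzm$dz) / (2 * hz)),
           2, 2)
  }
}
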