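# Equilibrium location by exact 1D reduction.
#
# Dividing the two fixed-point conditions y*D = alpha(nu + 1/(1+z^2)) and
# z*D = alpha(nu + 1/(1+y^2)) (D the shared resource denominator) shows that
# every equilibrium with alpha > 0 satisfies g(y) = g(z) with
# g(v) = v (nu + 1/(1+v^2)).  Factoring the diagonal root z = y out of the
# resulting cubic leaves the off-diagonal branch quadratic
#     nu (1+y^2) z^2 - y z + (1 + nu (1+y^2)) = 0,
# which collapses to the classic z = 1/y when nu = 0.  Equilibria are thus
# roots of scalar residuals on the diagonal and on (at most two) off-diagonal
# branches, located by dense sign-scan plus uniroot polish.

# residual of fy = 0 scaled by the denominator (same roots, better behaved):
# alpha (nu + h(z)) - y * D(y, z)
.eq_residual <- function(y, z, alpha, beta, nu, beta_c) {
  hy <- .hill(y)
  hz <- .hill(z)
  alpha * (nu + hz) - y * (1 + beta * (2 * nu + hy + hz) + beta_c)
}

# off-diagonal branch z(y); sign = +1/-1 picks the quadratic root.
# Returns NA where the branch does not exist (negative discriminant).
.branch_z <- function(y, nu, sign) {
  if (nu == 0) {
    z <- ifelse(y > 0, 1 / y, NA_real_)
    if (sign < 0) z <- rep(NA_real_, length(y))  # single branch at nu = 0
    return(z)
  }
  a2 <- nu * (1 + y * y)
  disc <- y * y - 4 * a2 * (1 + a2)
  ifelse(disc >= 0, (y + sign * sqrt(pmax(disc, 0))) / (2 * a2), NA_real_)
}

# y-interval(s) on which the off-diagonal branch exists.  In u = y^2 the
# discriminant is the concave quadratic
#   -4 nu^2 u^2 + (1 - 4 nu (1 + 2 nu)) u - 4 nu (1 + nu) >= 0,
# solved in closed form; for nu = 0 the branch z = 1/y exists for all y > 0.
.branch_support <- function(nu, ymax) {
  if (nu == 0) return(matrix(c(0, ymax), 1))
  A <- -4 * nu^2
  B <- 1 - 4 * nu * (1 + 2 * nu)
  C <- -4 * nu * (1 + nu)
  disc <- B * B - 4 * A * C
  if (disc <= 0 || B <= 0) return(NULL)
  u <- sort((-B + c(1, -1) * sqrt(disc)) / (2 * A))
  if (u[2] <= 0) return(NULL)
  lo <- sqrt(max(u[1], 0))
  hi <- sqrt(u[2])
  if (lo >= ymax) return(NULL)
  matrix(c(lo, min(hi, ymax)), 1)
}

# locate sign changes of res (NA-tolerant) over grid ys, polish with uniroot
.scan_roots <- function(fun, ys, res) {
  ok <- is.finite(res)
  roots <- numeric(0)
  idx <- which(ok[-length(ok)] & ok[-1] &
                 res[-length(res)] * res[-1] <= 0 &
                 (res[-length(res)] != 0 | res[-1] != 0))
  for (i in idx) {
    r <- tryCatch(
      stats::uniroot(fun, c(ys[i], ys[i + 1]),
                     f.lower = res[i], f.upper = res[i + 1],
                     tol = .Machine$double.eps^0.75)$root,
      error = function(e) NA_real_)
    if (is.finite(r)) roots <- c(roots, r)
  }
  # exact zeros on grid nodes (rare)
  roots <- c(roots, ys[ok & res == 0])
  roots
}

.classify_eigen <- function(y, z, alpha, beta, nu, beta_c) {
  j <- .jacobian(y, z, alpha, beta, nu, beta_c)
  tr <- j$dfy_dy + j$dfz_dz
  det <- j$dfy_dy * j$dfz_dz - j$dfy_dz * j$dfz_dy
  disc <- tr * tr / 4 - det
  if (disc >= 0) {
    re <- c(tr / 2 - sqrt(disc), tr / 2 + sqrt(disc))
    im <- 0
  } else {
    re <- c(tr / 2, tr / 2)
    im <- sqrt(-disc)
  }
  n_neg <- sum(re < 0)
  label <- if (n_neg == 2) "stable" else if (n_neg == 1) "saddle" else "unstable"
  if (any(abs(re) < 1e-9)) {
    warning("near-marginal eigenvalue at equilibrium (", signif(y, 6), ", ",
            signif(z, 6), "); labelled by sign as '", label, "'",
            call. = FALSE)
  }
  list(re1 = re[1], re2 = re[2], im = im, label = label)
}

#' Locate and classify all equilibria of a toggle switch
#'
#' Finds every nonnegative equilibrium of the reduced toggle model by an
#' exact reduction to scalar root-finding: the diagonal `z = y` and the
#' off-diagonal branches of the relation `g(y) = g(z)`,
#' `g(v) = v(nu + 1/(1+v^2))`, are each scanned densely for sign changes of
#' the fixed-point residual and polished with [stats::uniroot()].  Each root
#' is classified by the eigenvalues of the analytic Jacobian.
#'
#' @param params A [toggle_params()] object.
#' @param tol Acceptance tolerance on the residual norm `||rhs||` at a
#'   polished root; roots failing it are kept but flagged `converged = FALSE`.
#' @param n_scan Number of sign-scan points per branch (default 2000; the
#'   reduced residual has at most quintic-like root structure).
#' @param dedup_tol Euclidean distance under which two polished roots are
#'   considered the same equilibrium.
#' @return An object of class `equilibrium_set`: a list with `equilibria`
#'   (data frame with columns `y`, `z`, `eig1`, `eig2`, `eig_im`, `label`,
#'   `residual`, `converged`), `stability_class` (one of `"monostable"`,
#'   `"bistable"`, `"tristable"`, `"unresolved"`), `n_stable`, and `params`.
#' @examples
#' find_equilibria(toggle_params(alpha = 10))  # bistable pair plus saddle
#' @export
find_equilibria <- function(params, tol = 1e-8, n_scan = 2000,
                            dedup_tol = 1e-6) {
  params <- as_toggle_params(params)
  stopifnot(tol > 0)
  a <- params$alpha; b <- params$beta; nu <- params$nu; bc <- params$beta_c

  if (a == 0) {
    cls <- .classify_eigen(0, 0, a, b, nu, bc)
    eq <- data.frame(y = 0, z = 0, eig1 = cls$re1, eig2 = cls$re2,
                     eig_im = cls$im, label = cls$label, residual = 0,
                     converged = TRUE, stringsAsFactors = FALSE)
    return(structure(list(equilibria = eq, stability_class = "monostable",
                          n_stable = 1L, params = params),
                     class = "equilibrium_set"))
  }

  ymax <- a * (1 + nu) + 1
  ys <- seq(0, ymax, length.out = n_scan + 1)

  # diagonal branch
  fd <- function(y) .eq_residual(y, y, a, b, nu, bc)
  pts <- rbind(diag = cbind(y = .scan_roots(fd, ys, fd(ys)), sign = NA))
  roots <- lapply(pts[, 1], function(y) c(y, y))

  # off-diagonal branches, scanned densely over their analytic support
  support <- .branch_support(nu, ymax)
  if (!is.null(support)) {
    for (sgn in if (nu == 0) 1 else c(1, -1)) {
      fb <- function(y) .eq_residual(y, .branch_z(y, nu, sgn), a, b, nu, bc)
      for (k in seq_len(nrow(support))) {
        lo <- max(support[k, 1], ymax * 1e-12)
        hi <- support[k, 2]
        ysb <- seq(lo, hi, length.out = n_scan + 1)
        if (nu == 0) {
          # resolve the small-y tail of z = 1/y (roots down to ~ 1/alpha)
          ysb <- sort(unique(c(exp(seq(log(ymax * 1e-7), log(ysb[2]),
                                       length.out = 50)), ysb)))
        }
        rb <- .scan_roots(fb, ysb, fb(ysb))
        roots <- c(roots, lapply(rb, function(y) c(y, .branch_z(y, nu, sgn))))
      }
    }
  }

  # mirror completion: the set is symmetric under y <-> z by construction
  roots <- c(roots, lapply(roots, rev))

  # polish in 2D with Newton steps (the scalar branch roots are accurate in
  # y, but mapping z through steep branch functions can amplify the error)
  roots <- lapply(roots, function(r) {
    if (!all(is.finite(r))) return(r)
    for (it in 1:8) {
      f <- .rhs(r[1], r[2], a, b, nu, bc)
      if (f$dy^2 + f$dz^2 < 1e-26) break
      j <- .jacobian(r[1], r[2], a, b, nu, bc)
      det_j <- j$dfy_dy * j$dfz_dz - j$dfy_dz * j$dfz_dy
      if (!is.finite(det_j) || abs(det_j) < 1e-14) break
      r_new <- c(r[1] - ( j$dfz_dz * f$dy - j$dfy_dz * f$dz) / det_j,
                 r[2] - (-j$dfz_dy * f$dy + j$dfy_dy * f$dz) / det_j)
      if (any(!is.finite(r_new)) || any(r_new < -1e-9)) break
      r <- pmax(r_new, 0)
    }
    r
  })

  # deduplicate (mirror copies and diagonal/branch overlaps)
  uniq <- list()
  for (r in roots) {
    if (!all(is.finite(r)) || any(r < -dedup_tol)) next
    dup <- any(vapply(uniq, function(u) sqrt(sum((u - r)^2)) < dedup_tol,
                      logical(1)))
    if (!dup) uniq[[length(uniq) + 1]] <- pmax(r, 0)
  }

  if (length(uniq) == 0) {
    return(structure(list(equilibria = data.frame(), stability_class = "unresolved",
                          n_stable = 0L, params = params),
                     class = "equilibrium_set"))
  }

  eq <- do.call(rbind, lapply(uniq, function(r) {
    res <- sqrt(.rhs_norm2(r[1], r[2], a, b, nu, bc))
    cls <- .classify_eigen(r[1], r[2], a, b, nu, bc)
    data.frame(y = r[1], z = r[2], eig1 = cls$re1, eig2 = cls$re2,
               eig_im = cls$im, label = cls$label, residual = res,
               converged = res < tol, stringsAsFactors = FALSE)
  }))
  eq <- eq[order(eq$y), ]
  rownames(eq) <- NULL

  n_stable <- sum(eq$label == "stable" & eq$converged)
  stability_class <- switch(as.character(min(n_stable, 4)),
                            "0" = "unresolved", "1" = "monostable",
                            "2" = "bistable", "3" = "tristable",
                            "unresolved")
  structure(list(equilibria = eq, stability_class = stability_class,
                 n_stable = as.integer(n_stable), params = params),
            class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("equilibrium set (%s): %d equilibria, %d stable\n",
              x$stability_class, nrow(x$equilibria), x$n_stable))
  if (nrow(x$equilibria)) {
    print(cbind(round(x$equilibria[c("y", "z", "eig1", "eig2")], 6),
                label = x$equilibria$label))
  }
  invisible(x)
}
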