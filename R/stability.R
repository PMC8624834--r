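# Stability criteria, phase diagrams over parameter grids, and linear
# region-boundary fits.

#' Composite bistability statistic q = 2(1+beta)/alpha
#'
#' At zero promoter leakiness the switch is bistable exactly when `q < 1`;
#' resource competition acts against bistability by raising `q`.
#'
#' @param alpha Expression rate, must be positive.
#' @param beta Internal resource-usage weight.
#' @return Numeric, `2 * (1 + beta) / alpha` (vectorised).
#' @examples
#' q_statistic(4, 1)  # 1: on the bistability boundary
#' @export
q_statistic <- function(alpha, beta) {
  if (any(alpha <= 0)) stop("alpha must be positive (q diverges at alpha = 0)",
                            call. = FALSE)
  2 * (1 + beta) / alpha
}

#' Analytic bistability boundary in the (alpha, nu) plane at beta = 0
#'
#' Without resource competition, the monostable/bistable boundary is the
#' curve parameterised by `w >= 1`:
#' `alpha_w = (1+w^2)^2 / (2w)`, `nu_w = (w^2-1) / (1+w^2)^2`.
#' Points below the curve are bistable.  The leakiness coordinate attains
#' its maximum 1/8 at `w = sqrt(3)`: no leakiness above 0.125 admits
#' multistability.
#'
#' @param w Curve parameter, `w >= 1` (vectorised).
#' @return A data frame with columns `w`, `alpha_w`, `nu_w`.
#' @examples
#' analytic_boundary_beta0(1)  # alpha = 2, nu = 0: the classic threshold
#' @export
analytic_boundary_beta0 <- function(w) {
  if (any(!is.finite(w)) || any(w < 1)) stop("w must be >= 1", call. = FALSE)
  w2 <- w * w
  data.frame(w = w,
             alpha_w = (1 + w2)^2 / (2 * w),
             nu_w = (w2 - 1) / (1 + w2)^2)
}

#' Maximum promoter leakiness compatible with multistability
#'
#' Maximises the boundary curve coordinate `nu_w(w) = (w^2-1)/(1+w^2)^2`
#' over `w >= 1` numerically.  The maximum, 0.125, is the leakiness ceiling:
#' for larger `nu` the dynamics are monostable for every `alpha` and `beta`.
#'
#' @return A list with `nu_max` and the maximising `w_max` (`sqrt(3)`).
#' @export
nu_max_bistable <- function() {
  opt <- stats::optimize(function(w) (w^2 - 1) / (1 + w^2)^2,
                         interval = c(1, 100), maximum = TRUE,
                         tol = 1e-12)
  list(nu_max = opt$objective, w_max = opt$maximum)
}

#' Stability-class phase diagram over a parameter grid
#'
#' Classifies every cell of a two-parameter grid by counting stable
#' equilibria with [find_equilibria()].  Exactly two of `alpha`, `beta`,
#' `nu` must be vectors (the grid axes); the remaining arguments are held
#' fixed.  Solver failures in a cell are recorded as `"unresolved"`, never
#' dropped.
#'
#' @param alpha,beta,nu Scalars or strictly increasing grid vectors; exactly
#'   two must have length greater than one.
#' @param beta_c Fixed context burden for all cells.
#' @param n_scan Sign-scan density passed to [find_equilibria()].
#' @param tol Residual tolerance passed to [find_equilibria()].
#' @return An object of class `phase_diagram`: list with `grid` (long data
#'   frame: `alpha`, `beta`, `nu`, `class`), `axes` (names of the two swept
#'   parameters), and the fixed parameter values.
#' @examples
#' pd <- stability_class_grid(alpha = seq(1, 10, by = 1), beta = c(0, 1, 2))
#' table(pd$grid$class)
#' @export
stability_class_grid <- function(alpha, beta = 0, nu = 0, beta_c = 0,
                                 n_scan = 2000, tol = 1e-8) {
  axes <- c(alpha = length(alpha), beta = length(beta), nu = length(nu))
  swept <- names(axes)[axes > 1]
  if (length(swept) != 2) {
    stop("exactly two of alpha, beta, nu must be grid vectors", call. = FALSE)
  }
  for (v in list(alpha, beta, nu)) {
    if (length(v) > 1 && any(diff(v) <= 0)) {
      stop("grid vectors must be strictly increasing", call. = FALSE)
    }
  }
  grid <- expand.grid(alpha = alpha, beta = beta, nu = nu,
                      KEEP.OUT.ATTRS = FALSE)
  grid$class <- vapply(seq_len(nrow(grid)), function(i) {
    p <- toggle_params(grid$alpha[i], grid$beta[i], grid$nu[i], beta_c)
    tryCatch(
      suppressWarnings(
        find_equilibria(p, tol = tol, n_scan = n_scan)$stability_class),
      error = function(e) "unresolved")
  }, character(1))
  structure(list(grid = grid, axes = swept,
                 fixed = list(beta_c = beta_c,
                              alpha = if (length(alpha) == 1) alpha,
                              beta = if (length(beta) == 1) beta,
                              nu = if (length(nu) == 1) nu)),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("phase diagram over (%s, %s): %d cells\n",
              x$axes[1], x$axes[2], nrow(x$grid)))
  print(table(x$grid$class))
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  cls <- factor(x$grid$class,
                levels = c("monostable", "bistable", "tristable", "unresolved"))
  xv <- sort(unique(x$grid[[x$axes[1]]]))
  yv <- sort(unique(x$grid[[x$axes[2]]]))
  m <- matrix(as.integer(cls), nrow = length(xv))
  graphics::image(xv, yv, m, col = c("#d73027", "#1a9850", "#7b3294", "grey70"),
                  xlab = x$axes[1], ylab = x$axes[2], zlim = c(1, 4), ...)
  invisible(x)
}

# midpoints of class transitions scanned upward along the second axis
.transition_midpoints <- function(pd) {
  ax <- pd$axes
  g <- pd$grid
  xs <- sort(unique(g[[ax[1]]]))
  out <- list()
  for (x in xs) {
    col <- g[g[[ax[1]]] == x, ]
    col <- col[order(col[[ax[2]]]), ]
    cls <- col$class
    keep <- cls != "unresolved"
    col <- col[keep, ]; cls <- cls[keep]
    if (nrow(col) < 2) next
    ch <- which(cls[-1] != cls[-length(cls)])
    for (i in ch) {
      out[[length(out) + 1]] <- data.frame(
        x = x,
        y_mid = (col[[ax[2]]][i] + col[[ax[2]]][i + 1]) / 2,
        class_below = cls[i], class_above = cls[i + 1],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

#' Fit linear stability-region boundaries in the (alpha, beta) plane
#'
#' At a fixed leakiness, the monostable/bistable/tristable regions of the
#' `(alpha, beta)` plane are separated by straight lines
#' `alpha * a_i(nu) - beta + b_i(nu) = 0`.  This extracts the transition
#' fronts of a classified grid (midpoints between vertically adjacent cells
#' of different class), groups them by the ordered class pair they separate,
#' and fits `beta = a_i * alpha + b_i` to each front by least squares.
#'
#' @param pd A [stability_class_grid()] result with axes `(alpha, beta)`.
#' @param min_points Fronts supported by fewer transition midpoints than
#'   this are refused (too little data for a line).
#' @return A data frame with one row per front: `class_below`, `class_above`,
#'   the slope `a`, offset `b`, residual `rms` and point count `n`.
#' @examples
#' pd <- stability_class_grid(alpha = seq(2, 40, by = 2),
#'                            beta = seq(0, 12, by = 0.5))
#' fit_linear_boundaries(pd)  # single front: a = 1/2, b = -1
#' @export
fit_linear_boundaries <- function(pd, min_points = 3) {
  if (!identical(pd$axes, c("alpha", "beta"))) {
    stop("boundary fitting requires a diagram with axes (alpha, beta)",
         call. = FALSE)
  }
  tm <- .transition_midpoints(pd)
  if (nrow(tm) == 0 || length(unique(pd$grid$class)) < 2) {
    stop("diagram contains fewer than two stability classes; nothing to fit",
         call. = FALSE)
  }
  key <- paste(tm$class_below, tm$class_above, sep = "->")
  out <- lapply(split(tm, key), function(d) {
    if (nrow(d) < min_points) return(NULL)
    fit <- stats::lm(y_mid ~ x, data = d)
    data.frame(class_below = d$class_below[1], class_above = d$class_above[1],
               a = unname(stats::coef(fit)[2]), b = unname(stats::coef(fit)[1]),
               rms = sqrt(mean(stats::residuals(fit)^2)), n = nrow(d),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    stop("no transition front has enough points to fit", call. = FALSE)
  }
  # merge collinear fronts: when a wedge-shaped region (e.g. tristable) only
  # exists above a critical alpha, the same line is fitted from two distinct
  # class-pair segments; fronts whose positions agree within two grid steps
  # across the alpha range are one physical boundary
  beta_step <- mean(diff(sort(unique(pd$grid$beta))))
  a_rng <- range(pd$grid$alpha)
  repeat {
    merged <- FALSE
    if (nrow(out) >= 2) {
      for (i in seq_len(nrow(out) - 1)) {
        for (j in seq((i + 1), nrow(out))) {
          gap <- max(abs((out$a[i] - out$a[j]) * a_rng + out$b[i] - out$b[j]))
          if (gap < 2 * beta_step) {
            keep <- if (out$n[i] >= out$n[j]) i else j
            drop <- setdiff(c(i, j), keep)
            w <- out$n[c(keep, drop)]
            out$a[keep] <- sum(out$a[c(keep, drop)] * w) / sum(w)
            out$b[keep] <- sum(out$b[c(keep, drop)] * w) / sum(w)
            out$n[keep] <- sum(w)
            out <- out[-drop, ]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  rownames(out) <- NULL
  out[order(out$b + out$a * mean(range(pd$grid$alpha))), ]
}

#' Write a phase diagram to disk
#'
#' Writes the classified grid as a long-format CSV (`alpha`, `beta`, `nu`,
#' `class`) plus, when boundary fits are supplied, a JSON sidecar with the
#' fitted line coefficients.
#'
#' @param pd A [stability_class_grid()] result.
#' @param dir Output directory (created if missing).
#' @param boundaries Optional [fit_linear_boundaries()] result.
#' @return Invisibly, the paths written.
#' @export
write_phase_diagram <- function(pd, dir, boundaries = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "phase_diagram.csv")
  utils::write.csv(pd$grid, csv, row.names = FALSE)
  paths <- csv
  if (!is.null(boundaries)) {
    js <- file.path(dir, "boundaries.json")
    jsonlite::write_json(boundaries, js, digits = NA, dataframe = "rows")
    paths <- c(paths, js)
  }
  invisible(paths)
}
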