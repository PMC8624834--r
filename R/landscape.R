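# Quasi-potential landscape: V accumulated along deterministic trajectories
# via Delta V = -(fy^2 + fz^2) Delta t, barrier heights between metastable
# states, the barrier power law in q, and a grid landscape with a
# graph-based minimax cross-check.

# Fixed-step RK4 integrator over an ensemble of states (vectors y, z of
# length m), with per-column parameters allowed.  Accumulates the
# quasi-potential by the trapezoidal rule on -(fy^2+fz^2) using the same
# steps.  Stops early once every column has ||rhs|| < tol (or t_max).
.rk4_quasipotential <- function(y, z, alpha, beta, nu, beta_c,
                                dt, t_max, tol, record_every = 0) {
  m <- length(y)
  n_steps <- ceiling(t_max / dt)
  v <- numeric(m)
  n2 <- .rhs_norm2(y, z, alpha, beta, nu, beta_c)
  rec <- NULL
  if (record_every > 0) {
    n_rec <- floor(n_steps / record_every) + 1L
    rec <- list(t = numeric(n_rec), y = matrix(0, n_rec, m),
                z = matrix(0, n_rec, m), v = matrix(0, n_rec, m))
    rec$y[1, ] <- y; rec$z[1, ] <- z
    ri <- 1L
  }
  tol2 <- tol * tol
  step <- 0L
  while (step < n_steps) {
    step <- step + 1L
    k1 <- .rhs(y, z, alpha, beta, nu, beta_c)
    k2 <- .rhs(y + dt / 2 * k1$dy, z + dt / 2 * k1$dz, alpha, beta, nu, beta_c)
    k3 <- .rhs(y + dt / 2 * k2$dy, z + dt / 2 * k2$dz, alpha, beta, nu, beta_c)
    k4 <- .rhs(y + dt * k3$dy, z + dt * k3$dz, alpha, beta, nu, beta_c)
    y <- y + dt / 6 * (k1$dy + 2 * k2$dy + 2 * k3$dy + k4$dy)
    z <- z + dt / 6 * (k1$dz + 2 * k2$dz + 2 * k3$dz + k4$dz)
    n2_new <- .rhs_norm2(y, z, alpha, beta, nu, beta_c)
    v <- v - dt * (n2 + n2_new) / 2
    n2 <- n2_new
    if (record_every > 0 && step %% record_every == 0L) {
      ri <- ri + 1L
      rec$t[ri] <- step * dt
      rec$y[ri, ] <- y; rec$z[ri, ] <- z; rec$v[ri, ] <- v
    }
    if (max(n2) < tol2) break
  }
  if (record_every > 0) {
    keep <- seq_len(ri)
    rec <- lapply(rec, function(x) if (is.matrix(x)) x[keep, , drop = FALSE] else x[keep])
  }
  list(y = y, z = z, v = v, t = step * dt, rhs_norm = sqrt(n2),
       converged = n2 < tol2, record = rec)
}

#' Quasi-potential along a deterministic trajectory
#'
#' Integrates the toggle dynamics from `x0` with a fixed-step fourth-order
#' Runge-Kutta scheme and accumulates the quasi-potential with the same
#' steps, `Delta V = -(fy^2 + fz^2) Delta t` (trapezoidal rule), with
#' `V(x0) = 0`.  V is non-increasing along the trajectory: flows run
#' downhill on the landscape and halt at a fixed point.
#'
#' @param x0 Initial state `c(y, z)`.
#' @param params A [toggle_params()] object.
#' @param dt Fixed time step (dimensionless time).
#' @param t_max Time horizon; the trajectory must reach `||rhs|| < tol`
#'   before `t_max` or an error names the final residual norm.
#' @param tol Convergence tolerance on `||rhs||`.
#' @param record_every Store every this-many steps.
#' @return Object of class `potential_trajectory`: data frame with columns
#'   `t`, `y`, `z`, `V`, plus the attractor reached as attribute
#'   `"endpoint"`.
#' @examples
#' tr <- quasipotential_trajectory(c(3, 0.1), toggle_params(alpha = 10))
#' all(diff(tr$V) <= 0)
#' @export
quasipotential_trajectory <- function(x0, params, dt = 1e-3, t_max = 200,
                                      tol = 1e-8, record_every = 10) {
  params <- as_toggle_params(params)
  x0 <- .check_state(x0)
  stopifnot(dt > 0, t_max > dt)
  out <- .rk4_quasipotential(x0[1, 1], x0[1, 2], params$alpha, params$beta,
                             params$nu, params$beta_c, dt, t_max, tol,
                             record_every = record_every)
  if (!out$converged) {
    stop(sprintf(
      "trajectory did not reach a fixed point by t_max = %g; final ||rhs|| = %.3g",
      t_max, out$rhs_norm), call. = FALSE)
  }
  r <- out$record
  df <- data.frame(t = r$t, y = r$y[, 1], z = r$z[, 1], V = r$v[, 1])
  # ensure the converged endpoint is present
  if (df$t[nrow(df)] < out$t) {
    df <- rbind(df, data.frame(t = out$t, y = out$y, z = out$z, V = out$v))
  }
  structure(df, class = c("potential_trajectory", "data.frame"),
            endpoint = c(y = out$y, z = out$z), params = params)
}

# saddle-anchored barriers: integrate from saddle +/- eps along the unstable
# eigenvector; the accumulated drop to the attractor is the barrier of that
# attractor's basin through this saddle.
.unstable_direction <- function(y, z, params) {
  J <- toggle_jacobian(c(y, z), params)
  ev <- eigen(J)
  i <- which.max(Re(ev$values))
  v <- Re(ev$vectors[, i])
  v / sqrt(sum(v^2))
}

#' Potential barriers between metastable states
#'
#' For each saddle of a bistable or tristable switch, integrates the
#' quasi-potential along both sides of the saddle's unstable manifold
#' (started at `saddle + eps * unstable eigenvector`, scaled by the state
#' magnitude) down to the adjacent attractors.  The barrier for leaving the
#' basin of attractor `x_i` through that saddle is
#' `h_i = V(saddle) - V(x_i)`, the accumulated drop; for this planar system
#' the minimax path between adjacent basins passes through the saddle, so
#' this equals the inf-sup path definition of the barrier.
#'
#' @param params A [toggle_params()] object with bistable or tristable
#'   dynamics.
#' @param equilibria Optionally a precomputed [find_equilibria()] result.
#' @param dt,t_max,tol Integrator controls as in
#'   [quasipotential_trajectory()].
#' @param eps Relative offset of the start point from the saddle.
#' @return Object of class `barrier_report`: data frame with one row per
#'   (stable state, saddle) adjacency: source state, destination basin,
#'   saddle location and barrier `height`.
#' @examples
#' barrier_height(toggle_params(alpha = 4))  # symmetric pair, h ~ 0.507
#' @export
barrier_height <- function(params, equilibria = NULL, dt = 1e-3,
                           t_max = 1200, tol = 1e-8, eps = 1e-6) {
  params <- as_toggle_params(params)
  if (is.null(equilibria)) equilibria <- find_equilibria(params)
  if (!equilibria$stability_class %in% c("bistable", "tristable")) {
    stop("no barrier: dynamics are ", equilibria$stability_class,
         call. = FALSE)
  }
  eq <- equilibria$equilibria
  saddles <- eq[eq$label == "saddle", , drop = FALSE]
  stables <- eq[eq$label == "stable", , drop = FALSE]
  if (nrow(saddles) == 0) {
    stop("internal consistency error: multistable set without a saddle",
         call. = FALSE)
  }
  starts_y <- numeric(0); starts_z <- numeric(0); sad_idx <- integer(0)
  for (i in seq_len(nrow(saddles))) {
    v <- .unstable_direction(saddles$y[i], saddles$z[i], params)
    sc <- eps * max(1, sqrt(saddles$y[i]^2 + saddles$z[i]^2))
    starts_y <- c(starts_y, saddles$y[i] + sc * v[1], saddles$y[i] - sc * v[1])
    starts_z <- c(starts_z, saddles$z[i] + sc * v[2], saddles$z[i] - sc * v[2])
    sad_idx <- c(sad_idx, i, i)
  }
  # ||rhs|| at the offset start is of order eps; the stopping tolerance must
  # sit well below it or the integrator would halt at the saddle itself
  tol_eff <- min(tol, 0.05 * eps * max(1, max(saddles$y, saddles$z)))
  out <- .rk4_quasipotential(starts_y, starts_z, params$alpha, params$beta,
                             params$nu, params$beta_c, dt, t_max, tol_eff)
  if (!all(out$converged)) {
    stop(sprintf(
      "unstable-manifold trajectory did not converge; final ||rhs|| = %.3g",
      max(out$rhs_norm)), call. = FALSE)
  }
  rows <- lapply(seq_along(starts_y), function(k) {
    d2 <- (stables$y - out$y[k])^2 + (stables$z - out$z[k])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) > 1e-3 * max(1, abs(out$y[k]))) {
      stop("internal consistency error: trajectory endpoint matches no stable state",
           call. = FALSE)
    }
    data.frame(source_y = stables$y[j], source_z = stables$z[j],
               saddle_y = saddles$y[sad_idx[k]],
               saddle_z = saddles$z[sad_idx[k]],
               height = -out$v[k], stringsAsFactors = FALSE)
  })
  rep_df <- do.call(rbind, rows)
  # destination basin: the attractor reached on the other side of the saddle
  for (i in seq_len(nrow(rep_df))) {
    other <- if (i %% 2 == 1) i + 1 else i - 1
    rep_df$dest_y[i] <- rep_df$source_y[other]
    rep_df$dest_z[i] <- rep_df$source_z[other]
  }
  rep_df <- rep_df[c("source_y", "source_z", "dest_y", "dest_z",
                     "saddle_y", "saddle_z", "height")]
  structure(rep_df, class = c("barrier_report", "data.frame"),
            params = params, stability_class = equilibria$stability_class)
}

# vectorised barrier at nu = 0 for many (alpha, beta) sets at once.
# At nu = 0 the single saddle lies on the diagonal and its unstable
# direction is (1,-1)/sqrt(2) by symmetry; one descent suffices.
.barrier_nu0_vec <- function(alpha, beta, dt = 1e-3, t_max = 1000,
                             tol = 1e-8, eps = 1e-6) {
  m <- length(alpha)
  stopifnot(length(beta) == m)
  sad <- vapply(seq_len(m), function(i) {
    stats::uniroot(function(y) .eq_residual(y, y, alpha[i], beta[i], 0, 0),
                   c(1e-12, alpha[i] + 1),
                   tol = .Machine$double.eps^0.75)$root
  }, numeric(1))
  sc <- eps * pmax(1, sad * sqrt(2))
  tol_eff <- min(tol, 0.05 * eps * max(1, max(sad)))
  out <- .rk4_quasipotential(sad + sc / sqrt(2), sad - sc / sqrt(2),
                             alpha, beta, 0, 0, dt, t_max, tol_eff)
  if (!all(out$converged)) {
    stop("barrier trajectory did not converge for some parameter sets",
         call. = FALSE)
  }
  -out$v
}

#' Barriers across a sweep of q at zero leakiness
#'
#' Computes the potential barrier for a family of `(alpha, beta)` pairs
#' realising given values of the composite statistic `q = 2(1+beta)/alpha`.
#' By default each `q` is realised with the least resource load:
#' `alpha = max(alpha_min, 2/q)` and `beta = q * alpha / 2 - 1` (zero except
#' where the floor on `alpha` binds).
#'
#' @param q Vector of q values in (0, 1).
#' @param alpha,beta Optional explicit parameter vectors (same length as
#'   `q`); must reproduce `q`.
#' @param alpha_min Smallest expression rate used by the default pairing.
#' @param dt,t_max,tol,eps Integrator controls, see [barrier_height()].
#' @return Data frame with columns `q`, `alpha`, `beta`, `h`.
#' @export
barrier_q_curve <- function(q, alpha = NULL, beta = NULL, alpha_min = 3,
                            dt = 1e-3, t_max = 1000, tol = 1e-8, eps = 1e-6) {
  stopifnot(all(q > 0 & q < 1))
  if (is.null(alpha)) {
    alpha <- pmax(alpha_min, 2 / q)
    beta <- pmax(0, q * alpha / 2 - 1)
  } else {
    stopifnot(length(alpha) == length(q), length(beta) == length(q))
    if (max(abs(q_statistic(alpha, beta) - q)) > 1e-8) {
      stop("supplied (alpha, beta) do not realise the requested q values",
           call. = FALSE)
    }
  }
  h <- .barrier_nu0_vec(alpha, beta, dt = dt, t_max = t_max, tol = tol,
                        eps = eps)
  data.frame(q = q, alpha = alpha, beta = beta, h = h)
}

#' Fit the barrier power law h = psi1 * (1/q - 1)^psi2
#'
#' Ordinary least squares of `log h` on `log(1/q - 1)`; the prefactor is the
#' exponentiated intercept and the exponent the slope, each with standard
#' 95% confidence intervals from the regression.
#'
#' @param q Vector of q values in (0, 1).
#' @param h Matching barrier heights; nonpositive entries are dropped with a
#'   warning.
#' @param min_samples Minimum number of usable samples.
#' @return Object of class `barrier_powerlaw`: list with `psi1`, `psi2`,
#'   `ci_psi1`, `ci_psi2`, `n` and the underlying `lm` fit.
#' @examples
#' q <- seq(0.2, 0.8, by = 0.05)
#' fit_barrier_powerlaw(q, 0.545 * (1 / q - 1)^2.039)  # exact recovery
#' @export
fit_barrier_powerlaw <- function(q, h, min_samples = 10) {
  stopifnot(length(q) == length(h), all(q > 0 & q < 1))
  bad <- !(h > 0)
  if (any(bad)) {
    warning(sum(bad), " sample(s) with h <= 0 rejected", call. = FALSE)
    q <- q[!bad]; h <- h[!bad]
  }
  if (length(q) < min_samples) {
    stop("need at least ", min_samples, " samples with q in (0,1) and h > 0",
         call. = FALSE)
  }
  x <- log(1 / q - 1)
  fit <- stats::lm(log(h) ~ x)
  ci <- stats::confint(fit)
  structure(list(psi1 = exp(unname(stats::coef(fit)[1])),
                 psi2 = unname(stats::coef(fit)[2]),
                 ci_psi1 = exp(ci[1, ]), ci_psi2 = ci[2, ],
                 n = length(q), fit = fit),
            class = "barrier_powerlaw")
}

#' @export
print.barrier_powerlaw <- function(x, ...) {
  cat(sprintf("barrier power law h = psi1 (1/q - 1)^psi2 (n = %d)\n", x$n))
  cat(sprintf("  psi1 = %.4f  [%.4f, %.4f]\n", x$psi1, x$ci_psi1[1], x$ci_psi1[2]))
  cat(sprintf("  psi2 = %.4f  [%.4f, %.4f]\n", x$psi2, x$ci_psi2[1], x$ci_psi2[2]))
  invisible(x)
}

#' Quasi-potential landscape on a state-space grid
#'
#' Computes V at every grid node by integrating the quasi-potential from the
#' node down to its attractor, then aligning the per-basin surfaces so that
#' V is continuous at the saddle(s): each attractor is anchored at
#' `V = -h` (its barrier below the saddle level, taken as zero).  For
#' monostable parameters the single attractor anchors at 0.
#'
#' @param params A [toggle_params()] object.
#' @param y_range,z_range Numeric length-2 bounds; defaults cover all fixed
#'   points with a margin.
#' @param n Nodes per axis.
#' @param dt,t_max,tol Integrator controls.
#' @return Object of class `landscape_grid`: data frame `y`, `z`, `V`,
#'   `basin` (index into the stable states, NA where unresolved), with the
#'   equilibrium set and barrier report as attributes.
#' @export
landscape_grid <- function(params, y_range = NULL, z_range = NULL, n = 41,
                           dt = 2e-3, t_max = 200, tol = 1e-6) {
  params <- as_toggle_params(params)
  eqs <- find_equilibria(params)
  eq <- eqs$equilibria
  stables <- eq[eq$label == "stable", , drop = FALSE]
  if (is.null(y_range)) {
    top <- max(eq$y, eq$z, 1) * 1.4 + 0.5
    y_range <- c(0, top)
  }
  if (is.null(z_range)) z_range <- y_range
  ys <- seq(y_range[1], y_range[2], length.out = n)
  zs <- seq(z_range[1], z_range[2], length.out = n)
  nodes <- expand.grid(y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  out <- .rk4_quasipotential(nodes$y, nodes$z, params$alpha, params$beta,
                             params$nu, params$beta_c, dt, t_max, tol)
  # anchor each attractor
  anchor <- rep(0, nrow(stables))
  barriers <- NULL
  if (eqs$stability_class %in% c("bistable", "tristable")) {
    barriers <- barrier_height(params, equilibria = eqs, dt = dt,
                               t_max = t_max, tol = tol)
    for (i in seq_len(nrow(stables))) {
      hit <- which(abs(barriers$source_y - stables$y[i]) < 1e-6 &
                     abs(barriers$source_z - stables$z[i]) < 1e-6)
      if (length(hit)) anchor[i] <- -min(barriers$height[hit])
    }
  }
  basin <- rep(NA_integer_, nrow(nodes))
  V <- rep(NA_real_, nrow(nodes))
  conv <- out$converged
  if (nrow(stables) > 0 && any(conv)) {
    d2 <- sapply(seq_len(nrow(stables)), function(i) {
      (out$y - stables$y[i])^2 + (out$z - stables$z[i])^2
    })
    d2 <- matrix(d2, ncol = nrow(stables))
    bi <- max.col(-d2)
    near <- sqrt(d2[cbind(seq_along(bi), bi)]) < 1e-2 * max(1, max(stables$y))
    ok <- conv & near
    basin[ok] <- bi[ok]
    V[ok] <- anchor[bi[ok]] - out$v[ok]   # V(node) = V(attr) + drop
  }
  res <- data.frame(y = nodes$y, z = nodes$z, V = V, basin = basin)
  structure(res, class = c("landscape_grid", "data.frame"), params = params,
            equilibria = eqs, barriers = barriers, n = n)
}

#' Minimax-path barrier on a gridded landscape
#'
#' Independent cross-check of [barrier_height()]: on the aligned landscape
#' grid, the barrier between two basins is the minimax (lowest bottleneck)
#' path value.  Computed via the minimum spanning tree of the 8-neighbour
#' lattice with edge weights `max(V_u, V_v)`: the unique MST path between
#' the two basin minima realises the minimax bottleneck.
#'
#' @param ls A [landscape_grid()] result with at least two basins.
#' @param from,to Basin indices (default the two best-separated basins,
#'   i.e. 1 and the last).
#' @return List with `height` (bottleneck V minus the starting minimum),
#'   `bottleneck_V`, and the two minima used.
#' @export
landscape_minimax_barrier <- function(ls, from = NULL, to = NULL) {
  ok <- which(!is.na(ls$V))
  basins <- sort(unique(ls$basin[ok]))
  if (length(basins) < 2) stop("landscape has fewer than two basins", call. = FALSE)
  if (is.null(from)) from <- basins[1]
  if (is.null(to)) to <- basins[length(basins)]
  n <- attr(ls, "n")
  idx <- matrix(NA_integer_, n, n)
  idx[cbind(match(ls$y[ok], sort(unique(ls$y))),
            match(ls$z[ok], sort(unique(ls$z))))] <- seq_along(ok)
  edges <- integer(0)
  w <- numeric(0)
  shifts <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (s in seq_len(nrow(shifts))) {
    di <- shifts[s, 1]; dj <- shifts[s, 2]
    i1 <- seq_len(n - abs(di))
    j1 <- if (dj >= 0) seq_len(n - dj) else seq(1 + abs(dj), n)
    a <- idx[i1, j1, drop = FALSE]
    bmat <- idx[i1 + di, j1 + dj, drop = FALSE]
    keep <- !is.na(a) & !is.na(bmat)
    if (!any(keep)) next
    ea <- a[keep]; eb <- bmat[keep]
    edges <- c(edges, rbind(ea, eb))
    w <- c(w, pmax(ls$V[ok][ea], ls$V[ok][eb]))
  }
  g <- igraph::make_graph(edges, n = length(ok), directed = FALSE)
  igraph::E(g)$weight <- w
  mst <- igraph::mst(g)
  Vok <- ls$V[ok]; bok <- ls$basin[ok]
  n1 <- which(bok == from)[which.min(Vok[bok == from])]
  n2 <- which(bok == to)[which.min(Vok[bok == to])]
  path <- igraph::shortest_paths(mst, from = n1, to = n2, output = "epath",
                                 weights = NA)$epath[[1]]
  if (length(path) == 0) stop("basins are not connected on the grid", call. = FALSE)
  bottleneck <- max(igraph::E(mst)$weight[path])
  list(height = bottleneck - Vok[n1], bottleneck_V = bottleneck,
       from_min = Vok[n1], to_min = Vok[n2])
}
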