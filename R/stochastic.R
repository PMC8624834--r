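# Overdamped Langevin dynamics of the toggle switch: Euler-Maruyama with
# additive isotropic noise, reflecting boundary at zero, and dwell-time
# statistics of noise-driven transitions between the metastable states.

#' Configuration of a Langevin simulation
#'
#' @param noise Noise power `D` (diffusion coefficient of the additive
#'   isotropic noise); the step noise amplitude is `sqrt(2 D dt)`.
#' @param t_total Total simulated time per cell.
#' @param dt Euler-Maruyama step.
#' @param n_cells Number of independent trajectories.
#' @param seed Master seed; the full ensemble is reproducible bit-for-bit.
#' @param record_every Store every this-many steps.
#' @return An object of class `langevin_config`.
#' @export
langevin_config <- function(noise, t_total, dt = 1e-3, n_cells = 1,
                            seed = 1, record_every = 10) {
  stopifnot(noise >= 0, dt > 0, t_total > dt, n_cells >= 1, record_every >= 1)
  structure(list(noise = noise, t_total = t_total, dt = dt,
                 n_cells = as.integer(n_cells), seed = as.integer(seed),
                 record_every = as.integer(record_every)),
            class = "langevin_config")
}

#' Simulate the toggle switch under noise (Euler-Maruyama)
#'
#' Steps `x_{t+dt} = x_t + f(x_t) dt + sqrt(2 D dt) * xi` with standard
#' bivariate normal `xi`, reflecting at zero (absolute value) so repressor
#' levels stay nonnegative.  All cells advance in lockstep from one seeded
#' random stream, so a given seed yields a bit-identical ensemble.  With
#' `noise = 0` the scheme reduces to the deterministic Euler integrator.
#'
#' @param params A [toggle_params()] object.
#' @param config A [langevin_config()] object.
#' @param x0 Optional `n_cells x 2` matrix of initial states; by default
#'   cells start uniformly in `[0, alpha (1 + nu)]^2` (seeded).
#' @return Object of class `langevin_ensemble`: list with `time` (recorded
#'   times), matrices `y` and `z` (time x cells), `params`, `config`.
#' @export
simulate_langevin <- function(params, config, x0 = NULL) {
  params <- as_toggle_params(params)
  stopifnot(inherits(config, "langevin_config"))
  a <- params$alpha; b <- params$beta; nu <- params$nu; bc <- params$beta_c
  n <- config$n_cells
  dt <- config$dt
  n_steps <- ceiling(config$t_total / dt)
  sd_step <- sqrt(2 * config$noise * dt)
  set.seed(config$seed)
  if (is.null(x0)) {
    top <- max(a * (1 + nu), 1e-3)
    x0 <- cbind(stats::runif(n, 0, top), stats::runif(n, 0, top))
  } else {
    x0 <- .check_state(x0)
    if (nrow(x0) != n) stop("x0 must have n_cells rows", call. = FALSE)
  }
  y <- x0[, 1]; z <- x0[, 2]
  n_rec <- floor(n_steps / config$record_every) + 1L
  Y <- matrix(0, n_rec, n); Z <- matrix(0, n_rec, n)
  tms <- numeric(n_rec)
  Y[1, ] <- y; Z[1, ] <- z
  ri <- 1L
  scale_ref <- 0.5 * max(1, a * (1 + nu))
  warned <- FALSE
  for (step in seq_len(n_steps)) {
    f <- .rhs(y, z, a, b, nu, bc)
    if (!warned && step %% 100L == 1L &&
        max(abs(f$dy), abs(f$dz)) * dt > scale_ref) {
      warning("dt looks too large for these dynamics (|f| dt exceeds half the state scale)",
              call. = FALSE)
      warned <- TRUE
    }
    if (sd_step > 0) {
      xi <- stats::rnorm(2 * n)
      y <- abs(y + f$dy * dt + sd_step * xi[seq_len(n)])
      z <- abs(z + f$dz * dt + sd_step * xi[n + seq_len(n)])
    } else {
      y <- abs(y + f$dy * dt)
      z <- abs(z + f$dz * dt)
    }
    if (step %% config$record_every == 0L) {
      ri <- ri + 1L
      tms[ri] <- step * dt
      Y[ri, ] <- y; Z[ri, ] <- z
    }
  }
  structure(list(time = tms[seq_len(ri)],
                 y = Y[seq_len(ri), , drop = FALSE],
                 z = Z[seq_len(ri), , drop = FALSE],
                 params = params, config = config),
            class = "langevin_ensemble")
}

#' @export
print.langevin_ensemble <- function(x, ...) {
  cat(sprintf("Langevin ensemble: %d cells, %d recorded times up to t = %g (D = %g)\n",
              ncol(x$y), length(x$time), max(x$time), x$config$noise))
  invisible(x)
}

#' Write a thinned ensemble to CSV
#'
#' @param ensemble A [simulate_langevin()] result.
#' @param path Output CSV path; columns `t`, `cell`, `y`, `z`.
#' @param stride Keep every `stride`-th recorded time.
#' @return Invisibly, `path`.
#' @export
write_ensemble_csv <- function(ensemble, path, stride = 1) {
  keep <- seq(1, length(ensemble$time), by = stride)
  df <- data.frame(
    t = rep(ensemble$time[keep], ncol(ensemble$y)),
    cell = rep(seq_len(ncol(ensemble$y)), each = length(keep)),
    y = as.vector(ensemble$y[keep, ]),
    z = as.vector(ensemble$z[keep, ]))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Dwell and transition statistics between metastable states
#'
#' Assigns each recorded state to a basin by the sign of `y - z`, with a
#' neutral band `|y - z| < neutral_frac * gap` (gap = separation of the two
#' stable states along `y - z`) to avoid chatter double-counting.  A dwell
#' runs from first entry into one basin core until first entry into the
#' other; the first 10% of the record is discarded as burn-in.
#'
#' @param ensemble A [simulate_langevin()] result.
#' @param equilibria Optional precomputed [find_equilibria()] for the
#'   ensemble's parameters (must be bistable).
#' @param neutral_frac Width of the neutral band as a fraction of the gap.
#' @param burn_in Fraction of the record discarded before analysis.
#' @return Object of class `transition_stats`: list with `dwell_times`,
#'   `mean_transition_time` (`Inf` with `infinite_mean = TRUE` when no
#'   transition occurred), `n_transitions`, `occupancy` (fractions of core
#'   samples in the two basins, summing to 1).
#' @export
transition_times <- function(ensemble, equilibria = NULL, neutral_frac = 0.1,
                             burn_in = 0.1) {
  if (is.null(equilibria)) equilibria <- find_equilibria(ensemble$params)
  if (equilibria$stability_class != "bistable") {
    stop("transition statistics require bistable equilibria, got ",
         equilibria$stability_class, call. = FALSE)
  }
  st <- equilibria$equilibria
  st <- st[st$label == "stable", ]
  gap <- max(st$y - st$z) - min(st$y - st$z)   # 2 * |y* - z*|
  band <- neutral_frac * gap / 2
  keep <- ensemble$time >= burn_in * max(ensemble$time)
  tms <- ensemble$time[keep]
  s <- ensemble$y[keep, , drop = FALSE] - ensemble$z[keep, , drop = FALSE]
  dwells <- numeric(0)
  n_trans <- 0L
  occ <- c(plus = 0L, minus = 0L)
  for (cell in seq_len(ncol(s))) {
    lab <- ifelse(s[, cell] > band, 1L, ifelse(s[, cell] < -band, -1L, 0L))
    occ["plus"] <- occ["plus"] + sum(lab == 1L)
    occ["minus"] <- occ["minus"] + sum(lab == -1L)
    core <- lab != 0L
    if (!any(core)) next
    v <- lab[core]; tv <- tms[core]
    chg <- which(v[-1] != v[-length(v)])
    n_trans <- n_trans + length(chg)
    if (length(chg)) {
      entry <- c(tv[1], tv[chg + 1])
      dwells <- c(dwells, diff(entry))
    }
  }
  total_core <- sum(occ)
  structure(list(
    dwell_times = dwells,
    mean_transition_time = if (n_trans > 0) mean(dwells) else Inf,
    infinite_mean = n_trans == 0,
    n_transitions = n_trans,
    occupancy = if (total_core > 0) occ / total_core else occ * NA_real_,
    n_cells = ncol(s)),
    class = "transition_stats")
}

#' @export
print.transition_stats <- function(x, ...) {
  cat(sprintf("transitions: %d (mean dwell %s), occupancy +%0.3f / -%0.3f over %d cells\n",
              x$n_transitions,
              if (x$infinite_mean) "Inf" else sprintf("%.3g", x$mean_transition_time),
              x$occupancy[1], x$occupancy[2], x$n_cells))
  invisible(x)
}

#' Transition statistics as JSON
#'
#' @param stats A [transition_times()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
transition_stats_to_json <- function(stats, path) {
  jsonlite::write_json(
    list(mean_transition_time = stats$mean_transition_time,
         n_transitions = stats$n_transitions,
         occupancy = as.list(stats$occupancy),
         n_cells = stats$n_cells),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
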