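# Cell-to-cell heterogeneity: correlated normal parameter distributions,
# the analytic normal approximation to the distribution of the random
# stability statistics Q and Q_i, analytic vs Monte-Carlo stability
# fractions, and pooled population steady states.

#' Specification of a heterogeneous cell population
#'
#' Cells draw `(alpha, beta)` — and optionally the context burden
#' `beta_c` — from a (bi/tri)variate normal distribution.  `rho` is the
#' correlation between `alpha` and `beta`; correlations involving `beta_c`
#' default to zero.
#'
#' @param mu_alpha,mu_beta Means (mu_alpha must be positive).
#' @param sigma_alpha,sigma_beta Standard deviations (nonnegative).
#' @param rho Correlation of `alpha` and `beta`, in `[-1, 1]`.
#' @param mu_beta_c,sigma_beta_c Context-burden mean and SD (0 = isolated
#'   switch, bivariate model).
#' @param rho_alpha_bc,rho_beta_bc Correlations of `beta_c` with `alpha` and
#'   `beta`.
#' @param n_cells Number of cells to draw.
#' @param seed Seed for reproducible sampling.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(mu_alpha, mu_beta, sigma_alpha = 0,
                            sigma_beta = 0, rho = 0,
                            mu_beta_c = 0, sigma_beta_c = 0,
                            rho_alpha_bc = 0, rho_beta_bc = 0,
                            n_cells = 1000, seed = 1) {
  stopifnot(mu_alpha > 0, mu_beta >= 0, sigma_alpha >= 0, sigma_beta >= 0,
            abs(rho) <= 1, mu_beta_c >= 0, sigma_beta_c >= 0,
            abs(rho_alpha_bc) <= 1, abs(rho_beta_bc) <= 1, n_cells >= 1)
  cor3 <- matrix(c(1, rho, rho_alpha_bc,
                   rho, 1, rho_beta_bc,
                   rho_alpha_bc, rho_beta_bc, 1), 3, 3)
  if (min(eigen(cor3, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("correlation matrix is not positive semidefinite", call. = FALSE)
  }
  structure(list(mu_alpha = mu_alpha, mu_beta = mu_beta,
                 sigma_alpha = sigma_alpha, sigma_beta = sigma_beta,
                 rho = rho, mu_beta_c = mu_beta_c,
                 sigma_beta_c = sigma_beta_c,
                 rho_alpha_bc = rho_alpha_bc, rho_beta_bc = rho_beta_bc,
                 n_cells = as.integer(n_cells), seed = as.integer(seed)),
            class = "population_spec")
}

.pop_cov <- function(spec) {
  s <- c(spec$sigma_alpha, spec$sigma_beta, spec$sigma_beta_c)
  cor3 <- matrix(c(1, spec$rho, spec$rho_alpha_bc,
                   spec$rho, 1, spec$rho_beta_bc,
                   spec$rho_alpha_bc, spec$rho_beta_bc, 1), 3, 3)
  diag(s) %*% cor3 %*% diag(s)
}

#' Draw a heterogeneous cell population
#'
#' Samples `n_cells` parameter sets from the normal model of
#' [population_spec()].  The normal is an approximation to intrinsically
#' positive parameters, so draws with `alpha <= 0`, `beta < 0` or
#' `beta_c < 0` are rejected and resampled; a warning reports rejection
#' rates above 1%.
#'
#' @param spec A [population_spec()] object.
#' @return Data frame with columns `cell_id`, `alpha`, `beta`, `beta_c`.
#' @export
sample_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  trivariate <- spec$mu_beta_c > 0 || spec$sigma_beta_c > 0
  mu <- c(spec$mu_alpha, spec$mu_beta, spec$mu_beta_c)
  Sigma <- .pop_cov(spec)
  k <- if (trivariate) 3 else 2
  n <- spec$n_cells
  draws <- matrix(NA_real_, n, k)
  need <- seq_len(n)
  n_rejected <- 0L
  for (round in 1:100) {
    if (length(need) == 0) break
    x <- MASS::mvrnorm(length(need), mu = mu[1:k],
                       Sigma = Sigma[1:k, 1:k, drop = FALSE])
    x <- matrix(x, ncol = k)
    ok <- x[, 1] > 0 & x[, 2] >= 0
    if (k == 3) ok <- ok & x[, 3] >= 0
    n_rejected <- n_rejected + sum(!ok)
    take <- which(ok)
    if (length(take)) {
      fill <- need[seq_along(take)]
      draws[fill, ] <- x[take, , drop = FALSE]
      need <- setdiff(need, fill)
    }
  }
  if (length(need) > 0) {
    stop("could not draw a valid population (rejection rate too high); ",
         "check means and SDs", call. = FALSE)
  }
  rate <- n_rejected / (n_rejected + n)
  if (rate > 0.01) {
    warning(sprintf(
      "%.1f%% of normal draws violated positivity and were resampled; the normal model is strained at these CVs",
      100 * rate), call. = FALSE)
  }
  data.frame(cell_id = seq_len(n), alpha = draws[, 1], beta = draws[, 2],
             beta_c = if (k == 3) draws[, 3] else 0)
}

#' Analytic CDF of the population statistic Q
#'
#' Normal approximation to `P(Q < q)` for `Q = 2(1+beta)/alpha` with
#' `(alpha, beta)` bivariate normal: the event `Q < q` is the half-plane
#' `2(1+beta) - q alpha < 0`, itself normal, giving
#' `Phi((q - mu_Q) / sigma_Q(q))` with `mu_Q = 2(1+mu_beta)/mu_alpha` and
#' `sigma_Q(q) = sqrt(q^2 sigma_alpha^2 + 4 sigma_beta^2 -
#' 4 q rho sigma_alpha sigma_beta) / mu_alpha`.
#'
#' @param spec A [population_spec()] object.
#' @param q Quantiles (vectorised).
#' @return `P(Q < q)`; degenerate SDs yield a step function at `mu_Q`.
#' @export
q_distribution_analytic <- function(spec, q) {
  stopifnot(inherits(spec, "population_spec"))
  mu_q <- 2 * (1 + spec$mu_beta) / spec$mu_alpha
  s2 <- q^2 * spec$sigma_alpha^2 + 4 * spec$sigma_beta^2 -
    4 * q * spec$rho * spec$sigma_alpha * spec$sigma_beta
  sig <- sqrt(pmax(s2, 0)) / spec$mu_alpha
  ifelse(sig > 0, stats::pnorm((q - mu_q) / sig),
         ifelse(q > mu_q, 1, ifelse(q < mu_q, 0, 0.5)))
}

#' Analytic CDF of the boundary statistic Q_i at leakiness nu
#'
#' For a fitted region boundary `beta = a_i alpha + b_i`, the statistic
#' `Q_i = (beta - b_i) / (alpha a_i)` crosses 1 exactly on the line.  Its
#' normal approximation mirrors [q_distribution_analytic()]:
#' `mu_i = (mu_beta - b_i)/(mu_alpha a_i)` and `sigma_i(q_i) =
#' sqrt(q_i^2 a_i^2 sigma_alpha^2 - 2 rho q_i a_i sigma_alpha sigma_beta +
#' sigma_beta^2) / (a_i mu_alpha)`.
#'
#' @param spec A [population_spec()] object.
#' @param qi Quantiles (vectorised).
#' @param a_i,b_i Boundary-line slope and offset (`a_i > 0`).
#' @return `P(Q_i < qi)`.
#' @export
qi_distribution_analytic <- function(spec, qi, a_i, b_i) {
  stopifnot(inherits(spec, "population_spec"), a_i > 0)
  mu_i <- (spec$mu_beta - b_i) / (spec$mu_alpha * a_i)
  s2 <- qi^2 * a_i^2 * spec$sigma_alpha^2 -
    2 * spec$rho * qi * a_i * spec$sigma_alpha * spec$sigma_beta +
    spec$sigma_beta^2
  sig <- sqrt(pmax(s2, 0)) / (a_i * spec$mu_alpha)
  ifelse(sig > 0, stats::pnorm((qi - mu_i) / sig),
         ifelse(qi > mu_i, 1, ifelse(qi < mu_i, 0, 0.5)))
}

.new_fractions <- function(p, method) {
  p <- pmax(p, 0)
  p <- p / sum(p)
  structure(list(p_mono = p[1], p_bi = p[2], p_tri = p[3], method = method),
            class = "stability_fractions")
}

#' @export
print.stability_fractions <- function(x, ...) {
  cat(sprintf("stability fractions (%s): mono %.4f, bi %.4f, tri %.4f\n",
              x$method, x$p_mono, x$p_bi, x$p_tri))
  invisible(x)
}

#' Analytic stability fractions of a heterogeneous population
#'
#' Probability that a random cell is monostable, bistable or tristable.
#' At `nu = 0` the single closed-form boundary `q = 1` gives
#' `p_bi = P(Q < 1)`.  For leaky promoters (`0 < nu < 0.125`) supply the
#' fitted linear boundaries at that leakiness; the region probabilities are
#' differences of the boundary half-plane probabilities
#' `P(Q_i < 1)` (lines sorted bottom-to-top in `beta`), so the three
#' fractions sum to one.  For `nu >= 0.125` the population is entirely
#' monostable.
#'
#' @param spec A [population_spec()] object (bivariate; context burden is
#'   handled by rescaling parameters upstream).
#' @param nu Promoter leakiness shared by all cells.
#' @param boundaries A [fit_linear_boundaries()] result at this `nu`;
#'   required when `0 < nu < 0.125`.
#' @return A `stability_fractions` object.
#' @export
stability_fractions_analytic <- function(spec, nu = 0, boundaries = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  if (nu >= 0.125) return(.new_fractions(c(1, 0, 0), "analytic"))
  if (nu == 0) {
    p_bi <- q_distribution_analytic(spec, 1)
    return(.new_fractions(c(1 - p_bi, p_bi, 0), "analytic"))
  }
  if (is.null(boundaries) || nrow(boundaries) == 0) {
    stop("fitted boundaries are required for 0 < nu < 0.125", call. = FALSE)
  }
  pos <- boundaries$b + boundaries$a * spec$mu_alpha
  ord <- order(pos)
  bnd <- boundaries[ord, ]
  p_below <- vapply(seq_len(nrow(bnd)), function(i) {
    qi_distribution_analytic(spec, 1, bnd$a[i], bnd$b[i])
  }, numeric(1))
  p_below <- cummax(p_below)   # guard tiny inversions of nearly parallel lines
  region_p <- diff(c(0, p_below, 1))
  region_class <- c(bnd$class_below[1], bnd$class_above)
  p <- c(mono = 0, bi = 0, tri = 0)
  for (i in seq_along(region_p)) {
    key <- switch(region_class[i], monostable = "mono", bistable = "bi",
                  tristable = "tri", NA_character_)
    if (!is.na(key)) p[key] <- p[key] + region_p[i]
  }
  .new_fractions(unname(p), "analytic")
}

#' Monte-Carlo stability fractions by per-cell classification
#'
#' The brute-force counterpart of [stability_fractions_analytic()]: classify
#' every sampled cell with [find_equilibria()] and count.
#'
#' @param cells A [sample_population()] data frame (or any data frame with
#'   `alpha`, `beta`, and optionally `beta_c` columns).
#' @param nu Promoter leakiness shared by all cells.
#' @param n_scan Sign-scan density per cell (the default is lighter than
#'   [find_equilibria()]'s because populations are large).
#' @return A `stability_fractions` object with attribute `"classes"` (the
#'   per-cell labels).
#' @export
stability_fractions_empirical <- function(cells, nu = 0, n_scan = 800) {
  stopifnot(all(c("alpha", "beta") %in% names(cells)))
  bc <- if ("beta_c" %in% names(cells)) cells$beta_c else rep(0, nrow(cells))
  cls <- vapply(seq_len(nrow(cells)), function(i) {
    suppressWarnings(find_equilibria(
      toggle_params(cells$alpha[i], cells$beta[i], nu, bc[i]),
      n_scan = n_scan)$stability_class)
  }, character(1))
  p <- c(mean(cls == "monostable"), mean(cls == "bistable"),
         mean(cls == "tristable"))
  out <- .new_fractions(p, "empirical")
  attr(out, "classes") <- cls
  out
}

#' Pooled population steady-state distribution of y - z
#'
#' Simulates every cell of a heterogeneous population to (stochastic)
#' steady state and pools the readout `y - z`, the quantity whose
#' population histogram diagnoses uni-, bi- or trimodality.  With
#' `noise = 0` each cell runs deterministically (RK4) from a random initial
#' condition in `[0, alpha(1+nu)]^2` so every basin is reachable; with
#' `noise > 0` cells follow Euler-Maruyama dynamics and the post-burn-in
#' samples are pooled.
#'
#' @param spec A [population_spec()] object.
#' @param nu Promoter leakiness shared by all cells.
#' @param noise Noise power D.
#' @param t_total,dt Simulation controls.
#' @param burn_in Fraction of the record discarded (noise > 0).
#' @param seed Seed for initial conditions and noise (defaults to the
#'   spec's).
#' @return Object of class `population_steady_state`: list with `samples`
#'   (pooled y - z values), `cells` (the drawn parameters), `n_dropped`
#'   (cells whose deterministic run failed to converge), and `modes`
#'   (result of [count_modes()]).
#' @export
population_steady_state <- function(spec, nu = 0, noise = 0, t_total = 150,
                                    dt = 5e-3, burn_in = 0.5, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  cells <- sample_population(spec)
  if (is.null(seed)) seed <- spec$seed + 1L
  set.seed(seed)
  n <- nrow(cells)
  top <- cells$alpha * (1 + nu)
  y <- stats::runif(n, 0, top)
  z <- stats::runif(n, 0, top)
  n_dropped <- 0L
  if (noise == 0) {
    out <- .rk4_quasipotential(y, z, cells$alpha, cells$beta, nu,
                               cells$beta_c, dt = dt, t_max = t_total,
                               tol = 1e-5)
    n_dropped <- sum(!out$converged)
    samples <- (out$y - out$z)[out$converged]
  } else {
    n_steps <- ceiling(t_total / dt)
    sd_step <- sqrt(2 * noise * dt)
    keep_from <- ceiling(burn_in * n_steps)
    samples_list <- list()
    stride <- max(1L, floor(n_steps / 200))
    for (step in seq_len(n_steps)) {
      f <- .rhs(y, z, cells$alpha, cells$beta, nu, cells$beta_c)
      xi <- stats::rnorm(2 * n)
      y <- abs(y + f$dy * dt + sd_step * xi[seq_len(n)])
      z <- abs(z + f$dz * dt + sd_step * xi[n + seq_len(n)])
      if (step >= keep_from && step %% stride == 0L) {
        samples_list[[length(samples_list) + 1L]] <- y - z
      }
    }
    samples <- unlist(samples_list)
  }
  structure(list(samples = samples, cells = cells, n_dropped = n_dropped,
                 nu = nu, noise = noise,
                 modes = count_modes(samples)),
            class = "population_steady_state")
}

#' @export
print.population_steady_state <- function(x, ...) {
  cat(sprintf("population steady state: %d pooled samples (%d cells dropped), %d mode(s)\n",
              length(x$samples), x$n_dropped, x$modes$n_modes))
  invisible(x)
}

#' Count modes of a pooled distribution
#'
#' Operational modality call: a fixed-bandwidth kernel density estimate
#' whose local maxima are kept if their topographic prominence (height above
#' the highest saddle separating them from a taller peak) exceeds
#' `prominence` times the global maximum.
#'
#' @param x Numeric samples.
#' @param bw Kernel bandwidth; default `bw.nrd0` of the samples.
#' @param prominence Relative prominence threshold.
#' @return List with `n_modes`, `locations`, and the `density` object.
#' @export
count_modes <- function(x, bw = NULL, prominence = 0.05) {
  if (length(x) < 10) return(list(n_modes = NA_integer_, locations = numeric(0)))
  if (is.null(bw)) bw <- stats::bw.nrd0(x)
  d <- stats::density(x, bw = bw, n = 512)
  v <- d$y
  loc_max <- which(diff(sign(diff(v))) == -2) + 1
  if (length(loc_max) == 0) loc_max <- which.max(v)
  keep <- logical(length(loc_max))
  for (i in seq_along(loc_max)) {
    p <- loc_max[i]
    taller <- loc_max[v[loc_max] > v[p]]
    if (length(taller) == 0) { keep[i] <- TRUE; next }
    # highest saddle between p and the nearest taller peak on each side
    sep <- vapply(taller, function(tp) {
      rng <- if (tp < p) v[tp:p] else v[p:tp]
      min(rng)
    }, numeric(1))
    prom <- v[p] - max(sep)
    keep[i] <- prom >= prominence * max(v)
  }
  list(n_modes = sum(keep), locations = d$x[loc_max[keep]], density = d)
}

#' Write a pooled histogram to CSV
#'
#' @param pss A [population_steady_state()] result.
#' @param path Output CSV path; columns `bin_center`, `count`.
#' @param breaks Passed to [graphics::hist()].
#' @return Invisibly, `path`.
#' @export
write_histogram_csv <- function(pss, path, breaks = 60) {
  h <- graphics::hist(pss$samples, breaks = breaks, plot = FALSE)
  utils::write.csv(data.frame(bin_center = h$mids, count = h$counts),
                   path, row.names = FALSE)
  invisible(path)
}
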