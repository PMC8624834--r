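test_that("zero noise reduces Euler-Maruyama to deterministic Euler", {
  p <- toggle_params(alpha = 6)
  cfg <- langevin_config(noise = 0, t_total = 1, dt = 0.01, n_cells = 1,
                         seed = 5, record_every = 1)
  x0 <- matrix(c(3, 0.5), 1)
  ens <- simulate_langevin(p, cfg, x0 = x0)
  # independent Euler oracle
  y <- 3; z <- 0.5
  for (i in 1:100) {
    f <- unname(toggle_rhs(c(y, z), p))
    y <- y + 0.01 * f[1]; z <- z + 0.01 * f[2]
  }
  expect_equal(ens$y[101, 1], y, tolerance = 1e-12)
  expect_equal(ens$z[101, 1], z, tolerance = 1e-12)
})

test_that("identical seeds give bit-identical ensembles", {
  p <- toggle_params(alpha = 10)
  cfg <- langevin_config(noise = 0.05, t_total = 5, dt = 5e-3, n_cells = 4,
                         seed = 11)
  e1 <- simulate_langevin(p, cfg)
  e2 <- simulate_langevin(p, cfg)
  expect_identical(e1$y, e2$y)
  expect_identical(e1$z, e2$z)
  cfg2 <- langevin_config(noise = 0.05, t_total = 5, dt = 5e-3, n_cells = 4,
                          seed = 12)
  expect_false(identical(simulate_langevin(p, cfg2)$y, e1$y))
})

test_that("bistable dynamics under small noise give a bimodal y - z", {
  p <- toggle_params(alpha = 10)
  cfg <- langevin_config(noise = 0.05, t_total = 60, dt = 5e-3, n_cells = 40,
                         seed = 21)
  ens <- simulate_langevin(p, cfg)
  keep <- ens$time > 20
  s <- as.vector(ens$y[keep, ] - ens$z[keep, ])
  expect_equal(count_modes(s)$n_modes, 2)
})

test_that("monostable dynamics keep y - z unimodal around zero", {
  p <- toggle_params(alpha = 1.6)            # q = 1.25
  cfg <- langevin_config(noise = 0.02, t_total = 60, dt = 5e-3, n_cells = 30,
                         seed = 22)
  ens <- simulate_langevin(p, cfg)
  keep <- ens$time > 20
  s <- as.vector(ens$y[keep, ] - ens$z[keep, ])
  m <- count_modes(s)
  expect_equal(m$n_modes, 1)
  expect_lt(abs(m$locations), 0.2)
})

test_that("steady-state marginals stabilise after burn-in", {
  p <- toggle_params(alpha = 10)
  cfg <- langevin_config(noise = 0.05, t_total = 120, dt = 5e-3, n_cells = 30,
                         seed = 23)
  ens <- simulate_langevin(p, cfg)
  keep <- which(ens$time > 12)
  half <- keep[seq_len(floor(length(keep) / 2))]
  rest <- setdiff(keep, half)
  ks <- suppressWarnings(stats::ks.test(as.vector(ens$y[half, ]),
                                        as.vector(ens$y[rest, ])))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("dwell times shorten with noise power", {
  p <- toggle_params(alpha = 2 / 0.7)
  dwell <- sapply(c(0.05, 0.1, 0.15), function(D) {
    cfg <- langevin_config(noise = D, t_total = 150, dt = 5e-3, n_cells = 20,
                           seed = 31)
    transition_times(simulate_langevin(p, cfg))$mean_transition_time
  })
  expect_true(all(diff(dwell) < 0))
})

test_that("deeper barriers hold trajectories longer at fixed noise", {
  d1 <- transition_times(simulate_langevin(
    toggle_params(2 / 0.55),
    langevin_config(noise = 0.12, t_total = 150, dt = 5e-3, n_cells = 20,
                    seed = 32)))
  d2 <- transition_times(simulate_langevin(
    toggle_params(2 / 0.85),
    langevin_config(noise = 0.12, t_total = 150, dt = 5e-3, n_cells = 20,
                    seed = 32)))
  expect_gt(d1$mean_transition_time, d2$mean_transition_time)
})

test_that("occupancy is symmetric for the symmetric switch", {
  p <- toggle_params(alpha = 2 / 0.75)
  cfg <- langevin_config(noise = 0.1, t_total = 400, dt = 5e-3, n_cells = 50,
                         seed = 33)
  ens <- simulate_langevin(p, cfg)
  st <- transition_times(ens)
  expect_gt(st$n_transitions, 1000)
  expect_equal(sum(st$occupancy), 1, tolerance = 1e-12)
  # two-sided binomial test at the 1% level on the cells' final basins
  # (independent across cells; the per-sample occupancies are autocorrelated)
  final <- ens$y[nrow(ens$y), ] - ens$z[nrow(ens$z), ]
  bt <- stats::binom.test(sum(final > 0), length(final), p = 0.5)
  expect_gt(bt$p.value, 0.01)
  expect_equal(st$occupancy[["plus"]], 0.5, tolerance = 0.1)
})

test_that("absent transitions are reported, not thrown", {
  p <- toggle_params(alpha = 10)             # deep wells
  cfg <- langevin_config(noise = 0.01, t_total = 10, dt = 5e-3, n_cells = 3,
                         seed = 34)
  st <- transition_times(simulate_langevin(p, cfg,
                                           x0 = cbind(c(9, 9, 9), c(0.1, 0.1, 0.1))))
  expect_equal(st$n_transitions, 0)
  expect_true(st$infinite_mean)
  expect_equal(st$mean_transition_time, Inf)
})

test_that("transition analysis requires bistable dynamics", {
  p <- toggle_params(alpha = 1)
  cfg <- langevin_config(noise = 0.05, t_total = 5, dt = 5e-3, n_cells = 2,
                         seed = 35)
  expect_error(transition_times(simulate_langevin(p, cfg)), "bistable")
})
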