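test_that("degenerate spread collapses the population onto the means", {
  spec <- population_spec(mu_alpha = 50, mu_beta = 5, n_cells = 20, seed = 1)
  cells <- sample_population(spec)
  expect_true(all(cells$alpha == 50))
  expect_true(all(cells$beta == 5))
  expect_true(all(cells$beta_c == 0))
})

test_that("seeded sampling is reproducible and matches the target moments", {
  spec <- population_spec(150, 10, 15, 1, rho = 0.5, n_cells = 5e4, seed = 40)
  c1 <- sample_population(spec)
  c2 <- sample_population(spec)
  expect_identical(c1, c2)
  expect_equal(mean(c1$alpha), 150, tolerance = 3 * 15 / sqrt(5e4) / 150 * 5)
  expect_equal(stats::cor(c1$alpha, c1$beta), 0.5,
               tolerance = 3 / sqrt(5e4) + 0.01)
})

test_that("positivity rejection warns when the normal model is strained", {
  spec <- population_spec(mu_alpha = 5, mu_beta = 1, sigma_alpha = 4,
                          sigma_beta = 1, n_cells = 500, seed = 41)
  expect_warning(sample_population(spec), "resampled")
  cells <- suppressWarnings(sample_population(spec))
  expect_true(all(cells$alpha > 0))
  expect_true(all(cells$beta >= 0))
})

test_that("invalid correlation structure is rejected", {
  expect_error(population_spec(10, 1, 1, 1, rho = 0.9, sigma_beta_c = 1,
                               rho_alpha_bc = -0.9, rho_beta_bc = 0.9),
               "positive semidefinite")
})

test_that("analytic Q-CDF matches the Monte-Carlo distribution at CV <= 10%", {
  spec <- population_spec(150, 10, 15, 1, rho = 0.5, n_cells = 1e5, seed = 42)
  cells <- sample_population(spec)
  qv <- q_statistic(cells$alpha, cells$beta)
  qs <- seq(quantile(qv, 0.02), quantile(qv, 0.98), length.out = 25)
  analytic <- q_distribution_analytic(spec, qs)
  empirical <- vapply(qs, function(q) mean(qv < q), numeric(1))
  expect_lt(max(abs(analytic - empirical)), 0.01)
  # mean of Q: 2(1 + 10)/150
  expect_equal(2 * (1 + spec$mu_beta) / spec$mu_alpha, mean(qv),
               tolerance = 0.01)
})

test_that("correlation between alpha and beta tightens the Q distribution", {
  vars <- sapply(c(0, 0.5, 0.9), function(r) {
    spec <- population_spec(150, 10, 15, 1, rho = r, n_cells = 5e4, seed = 43)
    cells <- sample_population(spec)
    stats::var(q_statistic(cells$alpha, cells$beta))
  })
  expect_true(all(diff(vars) < 0))
})

test_that("point-mass population at q = 0.5 is entirely bistable", {
  spec <- population_spec(mu_alpha = 16, mu_beta = 3, n_cells = 10, seed = 2)
  fr <- stability_fractions_analytic(spec)
  expect_equal(fr$p_mono, 0)
  expect_equal(fr$p_bi, 1)
  expect_equal(fr$p_tri, 0)
  expect_equal(fr$p_mono + fr$p_bi + fr$p_tri, 1, tolerance = 1e-9)
})

test_that("analytic bistable fraction matches per-cell classification (nu=0)", {
  spec <- population_spec(30, 12, 3, 1.2, rho = 0, n_cells = 2000, seed = 44)
  fa <- stability_fractions_analytic(spec)
  fe <- stability_fractions_empirical(sample_population(spec))
  expect_lt(abs(fa$p_bi - fe$p_bi), 0.02)
  expect_equal(fe$p_mono + fe$p_bi + fe$p_tri, 1, tolerance = 1e-12)
})

test_that("leaky-promoter fractions use fitted boundaries and sum to one", {
  pd <- stability_class_grid(alpha = seq(0, 300, length.out = 61),
                             beta = seq(0, 40, length.out = 41),
                             nu = 0.05, n_scan = 600)
  bl <- fit_linear_boundaries(pd)
  expect_gte(nrow(bl), 2)
  spec <- population_spec(150, 10, 15, 1, rho = 0, n_cells = 1500, seed = 45)
  fa <- stability_fractions_analytic(spec, nu = 0.05, boundaries = bl)
  fe <- stability_fractions_empirical(sample_population(spec), nu = 0.05)
  expect_equal(fa$p_mono + fa$p_bi + fa$p_tri, 1, tolerance = 1e-9)
  expect_lt(abs(fa$p_bi - fe$p_bi), 0.05)
  expect_lt(abs(fa$p_mono - fe$p_mono), 0.05)
  # leakiness suppresses bistability relative to the nu = 0 population
  expect_lt(fa$p_bi, stability_fractions_analytic(spec, nu = 0)$p_bi)
  expect_error(stability_fractions_analytic(spec, nu = 0.05), "boundaries")
  # beyond the leakiness ceiling everything is monostable
  expect_equal(stability_fractions_analytic(spec, nu = 0.2)$p_mono, 1)
})

test_that("pooled steady states diagnose population modality", {
  # fully bistable population: two outer peaks
  bi <- population_steady_state(
    population_spec(16, 3, 0.8, 0.15, n_cells = 300, seed = 46), nu = 0)
  expect_equal(bi$modes$n_modes, 2)

  # mixed monostable + bistable cells at moderate leakiness: middle peak too
  mix <- population_steady_state(
    population_spec(110, 9, 8, 1.5, n_cells = 400, seed = 47), nu = 0.05,
    t_total = 400, dt = 0.01)
  expect_equal(mix$modes$n_modes, 3)
  cls_mix <- stability_fractions_empirical(mix$cells, nu = 0.05)
  expect_gt(cls_mix$p_mono, 0.2)
  expect_gt(cls_mix$p_bi, 0.2)

  # dominantly tristable population under weak noise: three peaks arising
  # from single-cell dynamics, not from mixing
  tri <- population_steady_state(
    population_spec(200, 18.8, 2, 0.2, n_cells = 120, seed = 48), nu = 0.05,
    noise = 0.035, t_total = 200, dt = 0.01)
  expect_equal(tri$modes$n_modes, 3)
  cls <- stability_fractions_empirical(tri$cells, nu = 0.05)
  expect_gt(cls$p_tri, 0.5)
})

test_that("trivariate populations draw a heterogeneous context burden", {
  spec <- population_spec(100, 5, 10, 0.5, rho = 0.3, mu_beta_c = 2,
                          sigma_beta_c = 0.2, n_cells = 2e4, seed = 49)
  cells <- sample_population(spec)
  expect_equal(mean(cells$beta_c), 2, tolerance = 0.05)
  expect_equal(stats::sd(cells$beta_c), 0.2, tolerance = 0.05)
  # independence by default
  expect_lt(abs(stats::cor(cells$alpha, cells$beta_c)), 0.05)
})
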