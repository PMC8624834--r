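test_that("quasi-potential vanishes when starting at a fixed point", {
  eq <- find_equilibria(toggle_params(alpha = 10))
  st <- eq$equilibria[eq$equilibria$label == "stable", ][1, ]
  tr <- quasipotential_trajectory(c(st$y, st$z), toggle_params(alpha = 10),
                                  t_max = 5)
  expect_lt(max(abs(tr$V)), 1e-12)
})

test_that("V is non-increasing along every trajectory", {
  set.seed(301)
  for (i in 1:3) {
    p <- toggle_params(runif(1, 3, 30), runif(1, 0, 3), 0)
    x0 <- c(runif(1, 0, p$alpha), runif(1, 0, p$alpha))
    tr <- quasipotential_trajectory(x0, p, dt = 2e-3)
    expect_true(all(diff(tr$V) <= 1e-12))
    expect_lte(tr$V[nrow(tr)], 0)
  }
})

test_that("halving the step changes the accumulated V by less than 0.1%", {
  p <- toggle_params(alpha = 8, beta = 1)
  x0 <- c(4, 0.5)
  v1 <- utils::tail(quasipotential_trajectory(x0, p, dt = 2e-3)$V, 1)
  v2 <- utils::tail(quasipotential_trajectory(x0, p, dt = 1e-3)$V, 1)
  expect_lt(abs(v1 - v2) / abs(v2), 1e-3)
})

test_that("non-converging horizons raise an informative error", {
  expect_error(quasipotential_trajectory(c(9, 0.2), toggle_params(10),
                                         t_max = 0.01),
               "final \\|\\|rhs\\|\\|")
})

test_that("symmetric switches have equal barriers on both sides", {
  b <- barrier_height(toggle_params(alpha = 6, beta = 0.5))
  expect_equal(nrow(b), 2)
  expect_equal(b$height[1], b$height[2], tolerance = 1e-6)
  expect_true(all(b$height > 0))
})

test_that("barrier at q = 0.5 matches the frozen cross-checked value", {
  # 0.5065516 frozen from two independent integrators (fixed-step RK4 at
  # dt = 1e-3 and an adaptive high-order solver at rtol 1e-12); the
  # commonly quoted power-law approximation puts it near 0.545
  h <- min(barrier_height(toggle_params(alpha = 4))$height)
  expect_equal(h, 0.5065516, tolerance = 1e-4)
  expect_equal(h, 0.545, tolerance = 0.1)
})

test_that("barriers are insensitive to the saddle offset epsilon", {
  h1 <- min(barrier_height(toggle_params(4), eps = 1e-8)$height)
  h2 <- min(barrier_height(toggle_params(4), eps = 1e-4)$height)
  expect_equal(h1, h2, tolerance = 1e-3)
})

test_that("barrier declines monotonically in q and vanishes towards q = 1", {
  crv <- barrier_q_curve(seq(0.3, 0.95, length.out = 8))
  expect_true(all(diff(crv$h) < 0))
  expect_lt(crv$h[nrow(crv)], 0.01)
})

test_that("monostable parameters admit no barrier", {
  expect_error(barrier_height(toggle_params(alpha = 1)), "no barrier")
})

test_that("power-law fit recovers exact synthetic data to six digits", {
  q <- seq(0.2, 0.8, length.out = 15)
  h <- 0.545 * (1 / q - 1)^2.039
  fit <- suppressWarnings(fit_barrier_powerlaw(q, h))  # lm warns on a perfect fit
  expect_equal(fit$psi1, 0.545, tolerance = 1e-6)
  expect_equal(fit$psi2, 2.039, tolerance = 1e-6)
  h_noisy <- h * exp(stats::rnorm(length(h), sd = 0.01))
  expect_warning(fit_barrier_powerlaw(c(q, 0.5), c(h_noisy, -1)), "rejected")
})

test_that("landscape minima sit on the stable states; minimax agrees", {
  p <- toggle_params(alpha = 4)
  ls <- landscape_grid(p, n = 41)
  eq <- attr(ls, "equilibria")$equilibria
  st <- eq[eq$label == "stable", ]
  cell <- diff(sort(unique(ls$y)))[1]
  for (i in seq_len(nrow(st))) {
    sub <- ls[!is.na(ls$V) & ls$basin == ls$basin[
      which.min((ls$y - st$y[i])^2 + (ls$z - st$z[i])^2)], ]
    best <- sub[which.min(sub$V), ]
    expect_lt(sqrt((best$y - st$y[i])^2 + (best$z - st$z[i])^2),
              1.5 * cell)
  }
  mm <- landscape_minimax_barrier(ls)
  h <- min(barrier_height(p)$height)
  expect_equal(mm$height, h, tolerance = 0.05)
})

test_that("graph minimax and saddle-manifold barriers agree on random sets", {
  set.seed(302)
  for (i in 1:10) {
    q <- runif(1, 0.3, 0.7)
    beta <- runif(1, 0, 2)
    p <- toggle_params(2 * (1 + beta) / q, beta)
    ls <- landscape_grid(p, n = 31)
    mm <- landscape_minimax_barrier(ls)
    h <- min(barrier_height(p)$height)
    expect_equal(mm$height, h, tolerance = 0.05,
                 label = sprintf("q=%.2f beta=%.2f minimax", q, beta))
  }
})

test_that("monostable landscape has a single basin", {
  ls <- landscape_grid(toggle_params(alpha = 1.5), n = 21)
  expect_equal(length(unique(stats::na.omit(ls$basin))), 1)
})

test_that("tristable switches report barriers around the middle state", {
  b <- barrier_height(toggle_params(200, 18, 0.05))
  expect_equal(nrow(b), 4)   # two saddles, each bounding two basins
  expect_true(all(b$height > 0))
  # mirror symmetry of the two outer escape barriers
  outer <- b[abs(b$source_y - b$source_z) > 1, ]
  expect_equal(sort(outer$height)[1], sort(outer$height)[2], tolerance = 1e-5)
})
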