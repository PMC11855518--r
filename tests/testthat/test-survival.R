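test_that("dataset construction censors at the threshold and builds harmonics", {
  ev <- make_events(3, response = c(698, 290, 300), hour = c(0, 6, 12))
  d <- build_survival_data(ev, K = 2)
  expect_equal(d$time_s, c(300, 290, 300))
  expect_equal(d$censored, c(TRUE, FALSE, FALSE))
  X <- attr(d, "X")
  expect_equal(dim(X), c(3, 4))
  expect_equal(unname(X[1, ]), c(0, 1, 0, 1))          # hour 0
  expect_equal(unname(X[2, ]), c(1, 0, 0, -1), tolerance = 1e-12)  # hour 6
  expect_error(build_survival_data(ev, K = 0), "K")
})

test_that("likelihood reduces to the censored-exponential closed form", {
  basis <- ohcacover:::make_basis(upper = 300)
  lam <- 0.01
  model <- list(beta = c(0, 0, 0, 0), omega = rep(log(lam), basis$nbasis),
                y = 0)
  # one uncensored observation at t = 100: log(0.01) - 1
  ev <- make_events(1, response = 100, hour = 0)
  d <- build_survival_data(ev)
  expect_equal(survival_loglik(model, d, basis), log(lam) - lam * 100,
               tolerance = 1e-10)
  # all censored at 300, n = 7: -lambda * 300 * n, no event terms
  ev2 <- make_events(7, response = 1000, hour = c(0, 3, 6, 9, 12, 15, 18))
  d2 <- build_survival_data(ev2)
  expect_equal(survival_loglik(model, d2, basis), -lam * 300 * 7,
               tolerance = 1e-10)
})

test_that("likelihood agrees with survreg's censored exponential fit", {
  skip_if_not_installed("survival")
  set.seed(42)
  tt <- rexp(60, 1 / 250)
  ev <- make_events(60, response = tt, hour = runif(60, 0, 24))
  d <- build_survival_data(ev)
  sv <- survival::survreg(
    survival::Surv(d$time_s, !d$censored) ~ 1, dist = "exponential")
  lam_hat <- exp(-sv$coefficients[[1]])
  basis <- ohcacover:::make_basis(upper = 300)
  model <- list(beta = rep(0, 4), omega = rep(log(lam_hat), basis$nbasis),
                y = 0)
  expect_equal(survival_loglik(model, d, basis), sv$loglik[1],
               tolerance = 1e-6)
})

test_that("frailty at a cell without events does not change the likelihood", {
  grid <- make_grid(c(0, 0, 2000, 2000), 500)
  ev <- make_events(5, x = 250, y = 250, response = c(100, 200, 400, 150, 80))
  d <- build_survival_data(ev)
  attr(d, "cell") <- ohcacover:::match_cells(d$x_m, d$y_m, grid)
  basis <- ohcacover:::make_basis(upper = 300)
  y0 <- rep(0, nrow(grid$cells))
  m0 <- list(beta = rep(0, 4), omega = rep(log(0.005), basis$nbasis), y = y0)
  y1 <- y0
  y1[10] <- 2.5  # an unoccupied cell
  m1 <- m0; m1$y <- y1
  expect_identical(survival_loglik(m0, d, basis),
                   survival_loglik(m1, d, basis))
})

test_that("chain bookkeeping: retention arithmetic and validation", {
  expect_equal(n_retained(mcmc_control(50000, 10000, 490)), 81L)
  expect_equal(n_retained(mcmc_control(preset = "paper")), 81L)
  expect_equal(n_retained(mcmc_control(2000, 500, 5)), 300L)
  expect_error(mcmc_control(100, 200, 1), "nits")
  expect_error(mcmc_control(100, 50, 0), "thin")
})

test_that("MCMC is deterministic under a fixed seed", {
  grid <- make_grid(c(0, 0, 2000, 2000), 500)
  ev <- simulate_survival_events(60, grid, beta = rep(0, 4), seed = 3)
  d <- build_survival_data(ev)
  cfg <- mcmc_control(200, 50, 5, seed = 7)
  f1 <- spatial_delay_model(d, grid, mcmc = cfg)
  f2 <- spatial_delay_model(d, grid, mcmc = cfg)
  expect_identical(f1$samples, f2$samples)
  f3 <- spatial_delay_model(d, grid, mcmc = mcmc_control(200, 50, 5, seed = 8))
  expect_false(identical(f1$samples$beta, f3$samples$beta))
})

test_that("PEP equals the survivor function for constant-hazard samples", {
  grid <- make_grid(c(0, 0, 1000, 1000), 500)
  basis <- ohcacover:::make_basis(upper = 300)
  lam <- log(2) / 300
  n_cell <- nrow(grid$cells)
  fake <- structure(list(
    samples = list(
      beta = matrix(0, 5, 4),
      omega = matrix(log(lam), 5, basis$nbasis),
      y = matrix(0, 5, n_cell),
      eta = rep(100, 5)
    ),
    basis = basis, grid = grid, threshold_s = 300, K = 2
  ), class = "spatial_delay_model")
  pep <- compute_pep(fake)
  expect_equal(pep$pep, rep(0.5, n_cell), tolerance = 1e-10)
  # survivor 1 everywhere when the hazard is (numerically) zero
  fake$samples$omega[] <- -60
  expect_equal(compute_pep(fake)$pep, rep(1, n_cell), tolerance = 1e-10)
})

test_that("PEP is monotone in an additive frailty shift and stable to relabeling", {
  grid <- make_grid(c(0, 0, 1500, 1500), 500)
  basis <- ohcacover:::make_basis(upper = 300)
  n_cell <- nrow(grid$cells)
  mk <- function(y_shift = 0, perm = seq_len(n_cell)) {
    y <- matrix(seq(-1, 1, length.out = n_cell)[perm] + y_shift, 3, n_cell,
                byrow = TRUE)
    structure(list(
      samples = list(beta = matrix(0, 3, 4),
                     omega = matrix(log(0.003), 3, basis$nbasis),
                     y = y, eta = rep(100, 3)),
      basis = basis, grid = grid, threshold_s = 300, K = 2
    ), class = "spatial_delay_model")
  }
  p0 <- compute_pep(mk(0))$pep
  p1 <- compute_pep(mk(1))$pep   # higher frailty -> faster arrival -> lower PEP
  expect_true(all(p1 < p0))
  perm <- rev(seq_len(n_cell))
  pp <- compute_pep(mk(0, perm))$pep
  expect_equal(pp, p0[perm])
})

test_that("relative risk is identically 1 with zero-width band when beta = 0", {
  grid <- make_grid(c(0, 0, 1000, 1000), 500)
  basis <- ohcacover:::make_basis(upper = 300)
  fake <- structure(list(
    samples = list(beta = matrix(0, 4, 4),
                   omega = matrix(log(0.002), 4, basis$nbasis),
                   y = matrix(0, 4, nrow(grid$cells)), eta = rep(100, 4)),
    basis = basis, grid = grid, threshold_s = 300, K = 2
  ), class = "spatial_delay_model")
  rr <- relative_risk_curve(fake)
  expect_equal(rr$median, rep(1, nrow(rr)), tolerance = 1e-12)
  expect_equal(rr$lo, rr$hi, tolerance = 1e-12)
  expect_equal(nrow(rr), 96)
})

test_that("rr curve day-average is 1 and the fit exposes standard methods", {
  grid <- make_grid(c(0, 0, 2000, 2000), 500)
  ev <- simulate_survival_events(80, grid, beta = c(0.5, 0, 0, 0), seed = 5)
  d <- build_survival_data(ev)
  fit <- spatial_delay_model(d, grid, mcmc = mcmc_control(400, 100, 3,
                                                          seed = 2))
  rr <- relative_risk_curve(fit)
  gm <- exp(mean(log(rr$median)))
  expect_lt(abs(gm - 1), 0.02)
  expect_true(all(rr$lo <= rr$median & rr$median <= rr$hi))

  expect_length(coef(fit), 4)
  s <- summary(fit)
  expect_s3_class(s, "summary.spatial_delay_model")
  pep <- predict(fit, type = "pep")
  expect_true(all(pep$pep >= 0 & pep$pep <= 1))
  sim <- simulate(fit, nsim = 2, seed = 1, n = 20)
  expect_length(sim, 2)
  expect_equal(nrow(sim[[1]]), 20)
  expect_output(print(fit), "spatial survival")
})

test_that("events outside the spatial field raise a domain error", {
  grid <- make_grid(c(0, 0, 1000, 1000), 500)
  ev <- simulate_survival_events(40, grid, beta = rep(0, 4), seed = 1)
  ev$x_m[1] <- 5000
  d <- build_survival_data(ev)
  expect_error(spatial_delay_model(d, grid, mcmc = mcmc_control(100, 10, 2)),
               "outside")
})

test_that("inverting the injected diurnal phase shifts the recovered peak by ~12 h", {
  grid <- make_grid(c(0, 0, 4000, 4000), 500)
  th0 <- 2 * pi * 11 / 24
  beta_true <- c(-0.8 * sin(th0), -0.8 * cos(th0), 0, 0)
  peak_of <- function(beta, seed) {
    ev <- simulate_survival_events(400, grid, beta = beta, y = 0,
                                   lambda0 = 0.002, seed = seed)
    fit <- spatial_delay_model(build_survival_data(ev), grid,
                               mcmc = mcmc_control(preset = "test",
                                                   seed = seed))
    rr <- relative_risk_curve(fit)
    rr$hour[which.max(rr$median)]
  }
  p1 <- peak_of(beta_true, 101)
  p2 <- peak_of(-beta_true, 101)
  shift <- abs(p1 - p2) %% 24
  shift <- min(shift, 24 - shift)
  expect_lt(abs(shift - 12), 3)
})

test_that("harmonic logistic cross-check tracks the Bayesian rr peak", {
  grid <- make_grid(c(0, 0, 2000, 2000), 500)
  th0 <- 2 * pi * 11 / 24
  beta_true <- c(-0.9 * sin(th0), -0.9 * cos(th0), 0, 0)
  ev <- simulate_survival_events(500, grid, beta = beta_true, seed = 4)
  d <- build_survival_data(ev)
  g <- exceedance_glm(d)
  expect_lt(abs(g$hour[which.max(g$rr)] - 11), 2)
  expect_lt(abs(exp(mean(log(g$rr))) - 1), 1e-6)
})
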