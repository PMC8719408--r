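test_that("linear predictor composes the shared/specific decomposition", {
  sim <- tiny_sim(seed = 2, n_rows = 2, n_cols = 2)
  d <- apomap:::panel_dims(sim$panel)
  zero <- model_params(alpha = rep(0, 4), beta_s = rep(0, d[["P"]]),
                       beta_st = rep(0, d[["Q"]]), n_areas = 4, n_periods = 4)
  expect_equal(linear_predictor(zero, sim$panel, 1, 1, 1), 0)
  expect_equal(plogis(linear_predictor(zero, sim$panel, 2, 3, 4)), 0.5)

  p3 <- zero; p3$alpha <- rep(-3, 4)
  expect_equal(linear_predictor(p3, sim$panel, 1, 2, 2), -3)
  expect_equal(plogis(-3), 1 / (1 + exp(3)), tolerance = 1e-12)

  pg <- zero; pg$gamma_s <- c(2, 1, 1, 0.5); pg$u_s <- c(0.5, 0, 0, -0.5)
  expect_equal(linear_predictor(pg, sim$panel, 1, 1, 1), 2 * 0.5)

  # the array form agrees with the scalar form cell by cell
  pr <- random_params(sim, seed = 4)
  eta <- linear_predictor(pr, sim$panel)
  for (cell in list(c(1, 1, 1), c(3, 2, 4), c(4, 4, 2))) {
    expect_equal(eta[cell[1], cell[2], cell[3]],
                 linear_predictor(pr, sim$panel, cell[1], cell[2], cell[3]))
  }
})

test_that("binomial log-likelihood matches the pmf and is additive in cells", {
  Y <- array(0L, c(1, 1, 1)); n <- matrix(1, 1, 1)
  pan <- panel_data(Y, n)
  p0 <- model_params(alpha = 0, n_areas = 1, n_periods = 1)
  expect_equal(log_likelihood(p0, pan), log(0.5))

  Y2 <- array(2L, c(1, 1, 1)); n2 <- matrix(10, 1, 1)
  pan2 <- panel_data(Y2, n2)
  expect_equal(log_likelihood(p0, pan2), log(45) - 10 * log(2))

  # masking one cell removes exactly its pmf term
  sim <- tiny_sim(seed = 6)
  pr <- random_params(sim, seed = 8)
  full <- log_likelihood(pr, sim$panel)
  panm <- sim$panel
  panm$mask[2, 3, 1] <- FALSE
  eta_cell <- linear_predictor(pr, sim$panel, 2, 3, 1)
  term <- dbinom(sim$panel$Y[2, 3, 1], sim$panel$n[2, 3],
                 plogis(eta_cell), log = TRUE)
  expect_equal(log_likelihood(pr, panm), full - term, tolerance = 1e-10)
})

test_that("log-prior and log-posterior match the brute-force oracle", {
  hyper <- hyperpriors()
  # 3-area path graph instance with hand-set parameters
  sim3 <- generate_dataset(apo_sim_config(n_rows = 1, n_cols = 3,
                                          n_periods = 2, n_outcomes = 2),
                           seed = 17)
  pr <- random_params(sim3, seed = 5)
  expect_equal(log_posterior(pr, sim3$panel, sim3$graph, hyper),
               oracle_log_posterior(pr, sim3$panel, sim3$graph, hyper),
               tolerance = 1e-8)

  # doubling a spatial field quadruples its ICAR penalty
  q1 <- icar_quadform(pr$u_s, sim3$graph)
  expect_equal(icar_quadform(2 * pr$u_s, sim3$graph), 4 * q1)

  # 4 areas x 3 periods x 2 outcomes with masked cells and both
  # interaction types
  sim4 <- generate_dataset(apo_sim_config(n_rows = 2, n_cols = 2,
                                          n_periods = 3, n_outcomes = 2,
                                          missing_frac = 0.15),
                           seed = 19)
  pr4 <- random_params(sim4, seed = 23)
  for (ia in c("iid", "rw1")) {
    expect_equal(
      log_posterior(pr4, sim4$panel, sim4$graph, hyper, interaction = ia),
      oracle_log_posterior(pr4, sim4$panel, sim4$graph, hyper,
                           interaction = ia),
      tolerance = 1e-8)
  }

  # likelihood dominance: a count far from n*pi lowers the posterior
  panbad <- sim4$panel
  i <- which(panbad$mask[, 1, 1])[1]
  panbad$Y[i, 1, 1] <- as.integer(round(panbad$n[i, 1] * 0.5))
  expect_lt(log_posterior(pr4, panbad, sim4$graph, hyper),
            log_posterior(pr4, sim4$panel, sim4$graph, hyper))

  # constraint violation is an internal error
  bad <- pr4; bad$u_t <- bad$u_t + 1
  expect_error(log_prior(bad, sim4$graph, hyper), "sum to zero")
})

test_that("constraint projection is idempotent and likelihood-invariant", {
  sim <- tiny_sim(seed = 10)
  pr <- random_params(sim, seed = 3)
  again <- apply_constraints(pr, sim$graph)
  for (f in c("alpha", "gamma_s", "gamma_t", "u_s", "u_t", "nu")) {
    expect_equal(again[[f]], pr[[f]], tolerance = 1e-12)
  }

  # product-one rule
  raw <- pr
  raw$gamma_t <- c(2, 2, 0.5, 0.5)
  out <- apply_constraints(raw, sim$graph)
  expect_equal(out$gamma_t, c(2, 2, 0.5, 0.5))
  raw$gamma_t <- c(2, 2, 2, 2)
  out <- apply_constraints(raw, sim$graph)
  expect_equal(out$gamma_t, rep(1, 4))
  expect_equal(prod(out$gamma_s), 1, tolerance = 1e-10)

  # unconstrained random state: likelihood unchanged by the projection
  set.seed(77)
  d <- apomap:::panel_dims(sim$panel)
  messy <- model_params(
    alpha = rnorm(4, -3), beta_s = rnorm(d[["P"]], 0, 0.1),
    beta_st = rnorm(d[["Q"]], 0, 0.1),
    gamma_s = exp(rnorm(4, 0.2, 0.4)), gamma_t = exp(rnorm(4, -0.1, 0.4)),
    u_s = rnorm(9, 1, 0.5), u_s_k = matrix(rnorm(36, -0.4, 0.3), 9, 4),
    u_t = rnorm(4, 0.3, 0.2), u_t_k = matrix(rnorm(16, 0.1, 0.1), 4, 4),
    nu = matrix(rnorm(36, 0.05, 0.05), 9, 4))
  cons <- apply_constraints(messy, sim$graph)
  expect_equal(log_likelihood(cons, sim$panel),
               log_likelihood(messy, sim$panel), tolerance = 1e-8)
  expect_silent(validate_params(cons, sim$graph))

  # literal additive spatial constraint is also likelihood-invariant
  cons_lit <- apply_constraints(messy, sim$graph, constraint = "literal")
  expect_equal(log_likelihood(cons_lit, sim$panel),
               log_likelihood(messy, sim$panel), tolerance = 1e-8)
  expect_equal(sum(cons_lit$gamma_s), 0, tolerance = 1e-10)
})
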