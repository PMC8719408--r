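test_that("chains are reproducible and constraint-respecting", {
  sim <- tiny_sim(seed = 4)
  cc <- chain_config(n_chains = 2, n_iter = 400, burn_in = 100, thin = 3,
                     seed = 9)
  fit <- suppressWarnings(run_chains(sim$panel, sim$graph, config = cc))
  expect_equal(nrow(fit$draws[[1]]), (400 - 100) %/% 3)

  refit <- suppressWarnings(run_chains(sim$panel, sim$graph, config = cc))
  expect_identical(fit$draws, refit$draws)
  expect_identical(fit$pi, refit$pi)

  # two chains with the same explicit seed are identical draws
  cs <- chain_config(n_chains = 2, n_iter = 300, burn_in = 100, thin = 2,
                     chain_seeds = c(7L, 7L))
  fs <- suppressWarnings(run_chains(sim$panel, sim$graph, config = cs))
  expect_identical(fs$draws[[1]], fs$draws[[2]])

  # every retained draw satisfies the identifiability constraints
  m <- as.matrix(fit)
  gs <- m[, grep("^gamma_s", colnames(m))]
  gt <- m[, grep("^gamma_t", colnames(m))]
  expect_lt(max(abs(rowSums(log(gs)))), 1e-8)
  expect_lt(max(abs(rowSums(log(gt)))), 1e-8)
  us <- m[, grep("^u_s\\[", colnames(m))]
  ut <- m[, grep("^u_t\\[", colnames(m))]
  expect_lt(max(abs(rowSums(us))), 1e-8)
  expect_lt(max(abs(rowSums(ut))), 1e-8)

  # initial C++ log-posterior equals the R reference implementation
  lp_r <- log_posterior(fit$init, sim$panel, sim$graph, hyperpriors())
  expect_equal(fit$lp0[[1]], lp_r, tolerance = 1e-8)
})

test_that("degenerate no-random-effects model matches the conjugate posterior", {
  # single outcome, flat data, only the intercept updated: posterior on
  # logit(p) should match the Beta-posterior logit mean (uniform prior)
  set.seed(33)
  N <- 4; J <- 2
  # counts large enough that the likelihood dominates the vague normal
  # prior, so the conjugate flat-prior oracle applies
  n <- matrix(5000L, N, J)
  p_true <- 0.05
  Y <- array(rbinom(N * J, 5000, p_true), c(N, J, 1))
  pan <- panel_data(Y, n)
  g <- generate_lattice(2, 2)
  cc <- chain_config(n_chains = 1, n_iter = 20000, burn_in = 2000, thin = 1,
                     seed = 2, store_pi = FALSE,
                     update = list(beta = FALSE, gamma = FALSE, u_s = FALSE,
                                   u_s_k = FALSE, u_t = FALSE, u_t_k = FALSE,
                                   nu = FALSE, tau = FALSE))
  fit <- run_chains(pan, g, config = cc)
  a <- as.vector(param_draws(fit, "alpha[1]"))
  post_a <- 1 + sum(Y); post_b <- 1 + sum(n) - sum(Y)
  analytic <- digamma(post_a) - digamma(post_b)  # E[logit p], p ~ Beta
  mc <- mc_error_check(a)
  expect_lt(abs(mean(a) - analytic), 3 * mc$mc_error)
})

test_that("precision full conditionals reproduce the analytic Gamma", {
  sim <- tiny_sim(seed = 14, n_rows = 4, n_cols = 4)
  u_fix <- sample_icar_field(sim$graph, precision = 2, seed = 3)
  cc <- chain_config(n_chains = 1, n_iter = 5200, burn_in = 200, thin = 1,
                     seed = 8, store_pi = FALSE,
                     init = list(u_s = u_fix),
                     update = list(alpha = FALSE, beta = FALSE, gamma = FALSE,
                                   u_s = FALSE, u_s_k = FALSE, u_t = FALSE,
                                   u_t_k = FALSE, nu = FALSE))
  fit <- run_chains(sim$panel, sim$graph, config = cc)
  tau_draws <- as.vector(param_draws(fit, "tau_us"))
  hy <- hyperpriors()
  shape <- hy$tau_shape + 0.5 * (sim$graph$n_areas - sim$graph$n_components)
  rate <- hy$tau_rate + 0.5 * icar_quadform(u_fix, sim$graph)
  ks <- suppressWarnings(ks.test(tau_draws, pgamma, shape = shape,
                                 rate = rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("Gelman-Rubin matches its formula oracle", {
  # hand-computed toy arrays
  x <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  n <- 4
  W <- mean(c(var(x[, 1]), var(x[, 2])))
  B <- n * var(colMeans(x))
  oracle <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(gelman_rubin(x), oracle, tolerance = 1e-12)

  # identical chains: B = 0 so Rhat = sqrt((n-1)/n) <= 1
  y <- rnorm(1000)
  expect_equal(gelman_rubin(cbind(y, y)), sqrt(999 / 1000))
  expect_lte(gelman_rubin(cbind(y, y)), 1)

  # well-separated chains blow up Rhat
  set.seed(1)
  far <- cbind(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(gelman_rubin(far), 5)

  expect_error(gelman_rubin(matrix(rnorm(10), ncol = 1)), "2 chains")
  expect_error(gelman_rubin(matrix(rnorm(2), ncol = 2)), "retained")
})

test_that("batch-means MC error implements the 5% stability rule", {
  set.seed(12)
  iid <- rnorm(10000)
  chk <- mc_error_check(iid)
  expect_equal(chk$ratio, 0.01, tolerance = 0.5)  # ~ 1/sqrt(10000)
  expect_true(chk$pass)

  # strongly autocorrelated chain fails
  ar <- as.vector(arima.sim(list(ar = 0.999), n = 1000))
  chk_ar <- mc_error_check(ar)
  expect_false(chk_ar$pass)

  # constant chain: degenerate, explicit fail
  chk_const <- mc_error_check(rep(1, 500))
  expect_true(chk_const$degenerate)
  expect_false(chk_const$pass)

  expect_error(mc_error_check(rnorm(50)), "100")
})

test_that("trace exports cover every scalar parameter", {
  sim <- tiny_sim(seed = 21, n_rows = 2, n_cols = 2)
  cc <- chain_config(n_chains = 2, n_iter = 200, burn_in = 100, thin = 2,
                     seed = 5, store_pi = FALSE)
  fit <- suppressWarnings(run_chains(sim$panel, sim$graph, config = cc))
  td <- trace_data(fit)
  expect_setequal(unique(td$parameter), fit$par_names)
  expect_equal(nrow(td), 2 * 50 * length(fit$par_names))
  f <- tempfile(fileext = ".csv")
  export_traces(fit, f, parameters = c("alpha[1]", "gamma_s[2]"))
  expect_true(file.exists(f))
  png_f <- tempfile(fileext = ".png")
  plot_traces(fit, c("alpha[1]", "tau_us"), file = png_f)
  expect_true(file.size(png_f) > 0)
  rep <- convergence_report(fit, c("alpha[1]", "alpha[2]"))
  expect_equal(nrow(rep), 2L)
  expect_true(all(is.finite(rep$rhat)))
})
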