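test_that("ICAR field sampler respects constraints and scale", {
  g <- generate_lattice(4, 5)
  f <- sample_icar_field(g, precision = 1, seed = 5)
  expect_equal(sum(f), 0, tolerance = 1e-10)

  # huge precision shrinks the field
  f_tight <- sample_icar_field(g, precision = 1e6, seed = 5)
  expect_lt(max(abs(f_tight)), 0.01)
  expect_error(sample_icar_field(g, precision = -1), "precision")

  # per-component zero sums on a disconnected graph
  gd <- build_adjacency(rbind(c("a", "b"), c("c", "d")),
                        c("a", "b", "c", "d", "e"))
  fd <- sample_icar_field(gd, 1, seed = 2)
  expect_equal(sum(fd[1:2]), 0, tolerance = 1e-10)
  expect_equal(sum(fd[3:4]), 0, tolerance = 1e-10)
  expect_equal(fd[5], 0)  # centered singleton
})

test_that("ICAR sampler matches the chi-square expectation of its quadratic form", {
  # E[tau * quadform] = rank(Laplacian) for a draw from the constrained GMRF
  g <- generate_lattice(10, 10)
  set.seed(99)
  tau <- 1
  q <- replicate(500, tau * icar_quadform(sample_icar_field(g, tau), g))
  se <- sd(q) / sqrt(length(q))
  expect_lt(abs(mean(q) - 99), 3 * se)
})

test_that("RW1 sampler is centered with unit-variance increments", {
  x <- sample_rw1(8, precision = 1, seed = 3)
  expect_equal(sum(x), 0, tolerance = 1e-10)
  expect_lt(max(abs(sample_rw1(8, 1e6, seed = 3))), 0.01)
  expect_error(sample_rw1(1, 1), "n_periods")

  # mean of the quadratic form = number of increments (3 for 4 periods)
  set.seed(123)
  q <- replicate(10000, rw1_quadform(sample_rw1(4, 1)))
  se <- sd(q) / sqrt(length(q))
  expect_lt(abs(mean(q) - 3), 3 * se)
})

test_that("generated cubes honor the model structure", {
  # all effects zero at alpha = 0 gives pi = 0.5
  cfg0 <- apo_sim_config(n_rows = 4, n_cols = 4, alpha = rep(0, 4),
                         beta_s = numeric(0), beta_st = numeric(0),
                         tau_us = 1e8, tau_usk = 1e8, tau_ut = 1e8,
                         tau_utk = 1e8, tau_nu = 1e8)
  sim0 <- generate_dataset(cfg0, seed = 21)
  ybar <- mean(sim0$panel$Y / array(sim0$panel$n, dim(sim0$panel$Y)))
  n_cells <- length(sim0$panel$Y)
  se <- sqrt(0.25 / mean(sim0$panel$n)) / sqrt(n_cells)
  expect_lt(abs(ybar - 0.5), 3 * se)

  # a strong shared field induces positive cross-outcome correlation of
  # area-level crude logits
  cfgs <- apo_sim_config(n_rows = 5, n_cols = 5, gamma_s = rep(1, 4),
                         tau_us = 0.25, tau_usk = 1e6, tau_nu = 1e6,
                         denom_range = c(3000, 5000))
  sims <- generate_dataset(cfgs, seed = 31)
  crude_logit <- apply(sims$panel$Y, c(1, 3), sum) /
    replicate(4, rowSums(sims$panel$n))
  crude_logit <- qlogis(pmin(pmax(crude_logit, 1e-6), 1 - 1e-6))
  cors <- cor(crude_logit)
  expect_true(all(cors[upper.tri(cors)] > 0))

  # missingness fraction materializes in the mask
  simm <- generate_dataset(apo_sim_config(n_rows = 5, n_cols = 5,
                                          missing_frac = 0.2), seed = 41)
  expect_equal(mean(simm$panel$mask), 0.8, tolerance = 0.01)
  expect_true(all(simm$panel$Y[!simm$panel$mask] == 0))
})

test_that("generation is bit-identical under a fixed seed and truth matches dims", {
  cfg <- apo_sim_config(n_rows = 3, n_cols = 3)
  a <- generate_dataset(cfg, seed = 5)
  b <- generate_dataset(cfg, seed = 5)
  expect_identical(a$panel, b$panel)
  expect_identical(a$truth$params, b$truth$params)
  expect_equal(dim(a$truth$pi), dim(a$panel$Y))
  expect_equal(length(a$truth$params$u_s), a$graph$n_areas)
})

test_that("large denominators recover the true risk surface", {
  cfg <- apo_sim_config(n_rows = 4, n_cols = 4, n_outcomes = 2,
                        denom_range = c(1e5, 1e5))
  sim <- generate_dataset(cfg, seed = 13)
  pi_hat <- sim$panel$Y / array(sim$panel$n, dim(sim$panel$Y))
  se <- sqrt(sim$truth$pi * (1 - sim$truth$pi) /
               array(sim$panel$n, dim(sim$panel$Y)))
  frac_in <- mean(abs(pi_hat - sim$truth$pi) <= 3 * se)
  expect_gte(frac_in, 0.99)
})

test_that("panel CSV round-trips counts, mask and covariates", {
  sim <- tiny_sim(seed = 3, missing_frac = 0.1)
  counts <- tempfile(fileext = ".csv")
  covs <- tempfile(fileext = ".csv")
  write_panel_csv(sim$panel, counts, covs)
  back <- read_panel_csv(counts, covs)
  expect_equal(back$Y, sim$panel$Y, ignore_attr = TRUE)
  expect_equal(back$n, sim$panel$n, ignore_attr = TRUE)
  expect_equal(back$mask, sim$panel$mask, ignore_attr = TRUE)
  expect_equal(unname(back$X_s), unname(sim$panel$X_s), tolerance = 1e-12)
  expect_equal(as.vector(back$X_st), as.vector(sim$panel$X_st),
               tolerance = 1e-12)
})

test_that("panel invariants are enforced", {
  Y <- array(0L, c(2, 2, 1)); n <- matrix(5, 2, 2)
  expect_s3_class(panel_data(Y, n), "apo_panel")
  Ybad <- Y; Ybad[1, 1, 1] <- 6L
  expect_error(panel_data(Ybad, n), "exceeds")
  nzero <- n; nzero[1, 1] <- 0
  Y1 <- Y; Y1[1, 1, 1] <- 1L; nz <- n; nz[1, 1] <- 0
  expect_error(panel_data(Y1, nz), "exceeds|n = 0")
  expect_error(panel_data(Y, n, X_s = matrix(NA_real_, 2, 1)), "non-finite")
})
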