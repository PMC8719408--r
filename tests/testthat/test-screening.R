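test_that("bivariate Poisson screening recovers a known rate ratio", {
  set.seed(101)
  n_rec <- 5000
  denom <- round(runif(n_rec, 500, 3000))
  x <- rnorm(n_rec)
  b0 <- -4; b1 <- 1  # true rate ratio e
  y <- rpois(n_rec, denom * exp(b0 + b1 * x))
  r <- fit_bivariate_poisson(y, log(denom), x, covariate = "xtest")
  expect_lt(abs(r$coefficient - b1), 3 * r$standard_error)
  expect_lt(r$wald_p, 1e-10)
  expect_equal(r$ci_upper - r$ci_lower, 2 * qnorm(0.975) * r$standard_error,
               tolerance = 1e-10)
  expect_true(r$converged)

  expect_error(fit_bivariate_poisson(y, log(denom), rep(1, n_rec)),
               "zero variance")
})

test_that("Wald p is invariant to affine rescaling of the covariate", {
  set.seed(5)
  denom <- round(runif(400, 500, 2000))
  x <- rnorm(400)
  y <- rpois(400, denom * exp(-4 + 0.3 * x))
  a <- fit_bivariate_poisson(y, log(denom), x)
  b <- fit_bivariate_poisson(y, log(denom), 100 * x - 7)
  expect_equal(a$wald_p, b$wald_p, tolerance = 1e-6)
  expect_equal(a$coefficient, 100 * b$coefficient, tolerance = 1e-6)
  expect_equal(a$standard_error, 100 * b$standard_error, tolerance = 1e-6)
})

test_that("type-I error of the screening Wald test is near nominal", {
  set.seed(202)
  n_rep <- 1000
  hits <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    denom <- round(runif(200, 500, 3000))
    x <- rnorm(200)
    y <- rpois(200, denom * exp(-4))  # null: no covariate effect
    hits[r] <- fit_bivariate_poisson(y, log(denom), x)$wald_p < 0.05
  }
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(mean(hits) - 0.05), 2 * mc_se + 1e-12)
})

test_that("selection applies the p threshold deterministically", {
  mk <- function(cov, p, dev = 100) {
    data.frame(covariate = cov, outcome = "o1", coefficient = 0,
               standard_error = 1, ci_lower = -2, ci_upper = 2,
               wald_p = p, deviance = dev, converged = TRUE)
  }
  covtab <- as.data.frame(matrix(rnorm(600), 100, 6))
  names(covtab) <- paste0("c", 1:6)
  res <- do.call(rbind, Map(mk, names(covtab),
                            c(0.01, 0.2, 0.03, 0.6, 0.04, 0.8)))
  sel <- select_covariates(res, covtab)
  expect_equal(sum(sel$selected), 3L)
  expect_setequal(sel$covariate[sel$selected], c("c1", "c3", "c5"))

  # all non-significant: empty selection
  res_ns <- do.call(rbind, Map(mk, names(covtab), rep(0.5, 6)))
  expect_equal(sum(select_covariates(res_ns, covtab)$selected), 0L)

  expect_error(select_covariates(res[0, ], covtab), "empty")
})

test_that("collinear significant pairs keep only the smaller-p member", {
  set.seed(9)
  z <- rnorm(200)
  covtab <- data.frame(c1 = z, c2 = z + rnorm(200, sd = 1e-6),
                       c3 = rnorm(200))
  res <- data.frame(covariate = c("c1", "c2", "c3"), outcome = "o1",
                    coefficient = 0, standard_error = 1, ci_lower = -2,
                    ci_upper = 2, wald_p = c(0.001, 0.01, 0.02),
                    deviance = c(50, 60, 70), converged = TRUE)
  sel <- select_covariates(res, covtab)
  expect_true(sel$selected[sel$covariate == "c1"])
  expect_false(sel$selected[sel$covariate == "c2"])
  expect_true(sel$dropped_collinear[sel$covariate == "c2"])
  expect_true(sel$selected[sel$covariate == "c3"])
})

test_that("panel-level screening finds the simulated covariate signal", {
  # strong covariate effects, modest random-effect noise
  cfg <- apo_sim_config(n_rows = 5, n_cols = 5, beta_s = c(0.3, 0),
                        beta_st = c(0.25, 0), tau_us = 50, tau_usk = 200,
                        tau_nu = 1e4, denom_range = c(2000, 4000))
  sim <- generate_dataset(cfg, seed = 55)
  scr <- screen_covariates(sim$panel)
  expect_true(all(c("xs1", "xst1") %in% scr$selected))
  # a screening row exists for every covariate x outcome pair
  expect_equal(nrow(scr$results), 4 * 4)
  # reported interval structure: one estimate + 95% interval per row
  expect_true(all(scr$results$ci_lower <= scr$results$coefficient &
                    scr$results$coefficient <= scr$results$ci_upper))
})
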