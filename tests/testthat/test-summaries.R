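test_that("yearly totals reproduce the published burden table margins", {
  ref <- apo_reference_counts()
  tot <- yearly_totals(ref)
  expect_equal(unname(tot$outcome_totals["low_birth_weight"]), 150803)
  expect_equal(unname(tot$outcome_totals["stillbirth"]), 63860)
  expect_equal(unname(tot$outcome_totals["preterm_birth"]), 91682)
  expect_equal(unname(tot$outcome_totals["neonatal_death"]), 35695)
  expect_equal(unname(tot$period_totals["2016"]), 88816)
  expect_equal(unname(tot$period_totals["2019"]), 101455)
  expect_equal(tot$grand_total, sum(ref$count))

  # panel method: missing cells contribute zero, completeness reported
  sim <- tiny_sim(seed = 9, missing_frac = 0.25)
  tp <- yearly_totals(sim$panel)
  expect_equal(sum(tp$by), sum(sim$panel$Y))
  expect_equal(tp$completeness, mean(sim$panel$mask))
  zero <- sim$panel; zero$Y[] <- 0L
  expect_equal(yearly_totals(zero)$grand_total, 0)
})

test_that("percent change matches the published temporal changes", {
  expect_equal(round(percent_change(88816, 101455), 1), 14.2)
  expect_equal(round(percent_change(38440, 46051), 1), 19.8)
  expect_equal(round(percent_change(23597, 27437), 1), 16.3)
  expect_equal(round(percent_change(16888, 17810), 1), 5.5)
  expect_equal(round(percent_change(9891, 10157), 1), 2.7)
  expect_equal(percent_change(5, 5), 0)
  rates <- apo_reference_stillbirth_rates()
  expect_equal(round(percent_change(rates[["first"]], rates[["last"]]), 1),
               -6.7)
  expect_error(percent_change(0, 10), "undefined")
})

test_that("rates per 100 / 1000 live births behave and label crude vs model-based", {
  expect_equal(rate_per(50, 1000, 1000), 50)
  # crude national low-birth-weight rate from the published totals: ~5.2 per
  # 100, distinct from the model-based 4.5
  crude <- rate_per(150803, apo_reference_live_births(), 100)
  expect_equal(round(crude, 1), 5.2)
  expect_error(rate_per(5, 0), "denominator")
})

test_that("per-area absolute differences rank and partition areas", {
  rates <- matrix(c(10, 10, 10, 10,
                    8, 10, 15, 10), ncol = 2,
                  dimnames = list(paste0("a", 1:4), c("2016", "2019")))
  ad <- area_absolute_difference(rates, "2016", "2019")
  expect_equal(ad$n_decline, 1L)
  expect_equal(ad$n_increase, 1L)
  expect_equal(ad$n_zero, 2L)
  expect_equal(ad$n_decline + ad$n_increase + ad$n_zero, 4L)
  expect_equal(ad$extremes$largest_increase$area_id, "a3")
  expect_equal(ad$extremes$largest_decline$area_id, "a1")

  # identical surfaces: all zero differences
  same <- area_absolute_difference(cbind(`2016` = rates[, 1],
                                         `2019` = rates[, 1]),
                                   "2016", "2019")
  expect_equal(same$n_decline, 0L)
  expect_true(all(same$table$difference == 0))

  # injected +5-point area tops the increase ranking
  r2 <- rates; r2["a2", "2019"] <- r2["a2", "2016"] + 50
  ad2 <- area_absolute_difference(r2, "2016", "2019")
  expect_equal(ad2$table$area_id[1], "a2")
})

test_that("shared-component surface is centered and recovers a strong gradient", {
  # pronounced shared spatial field, weak specific fields
  cfg <- apo_sim_config(n_rows = 6, n_cols = 6, tau_us = 0.5, tau_usk = 400,
                        tau_nu = 1e4, denom_range = c(3000, 5000),
                        beta_s = numeric(0), beta_st = numeric(0))
  sim <- generate_dataset(cfg, seed = 61)
  cc <- chain_config(n_chains = 2, n_iter = 4000, burn_in = 1000, thin = 5,
                     seed = 3, store_pi = FALSE)
  fit <- suppressWarnings(run_chains(sim$panel, sim$graph, config = cc))
  surf <- shared_component_surface(fit)
  expect_equal(nrow(surf$spatial), 36L)
  expect_lt(abs(sum(surf$spatial$median)), 0.2)
  expect_true(all(surf$spatial$lower <= surf$spatial$median &
                    surf$spatial$median <= surf$spatial$upper))
  rho <- cor(surf$spatial$median, sim$truth$params$u_s, method = "spearman")
  expect_gt(rho, 0.7)

  # rate table respects the interval ordering invariant
  cc_pi <- chain_config(n_chains = 1, n_iter = 800, burn_in = 300, thin = 5,
                        seed = 2)
  fit_pi <- suppressWarnings(run_chains(sim$panel, sim$graph, config = cc_pi))
  rt <- posterior_rate_table(fit_pi, sim$panel)
  expect_true(all(rt$lower <= rt$median & rt$median <= rt$upper))
  expect_equal(nrow(rt), 36 * 4 * 4)
})
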