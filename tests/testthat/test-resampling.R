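test_that("noise-free cohorts give a collapsed bootstrap CI at the true join", {
  rec <- make_piecewise(tau = 8)
  gf <- fit_growth_curve(data.frame(age = c(0, 10, 20), mass = c(1, 2, 3),
                                    group = "exact"))
  est <- bootstrap_critical_weight(rec, growth_fit = gf, n_boot = 100, seed = 1)
  expect_equal(est$age, 8, tolerance = 1e-8)
  expect_equal(c(est$age_ci_low, est$age_ci_high), c(8, 8), tolerance = 1e-8)
  expect_equal(est$mass, 1.8, tolerance = 1e-8)
  expect_equal(c(est$mass_ci_low, est$mass_ci_high), c(1.8, 1.8), tolerance = 1e-8)
  expect_equal(est$n_failed_boot, 0L)
})

test_that("CI endpoints are the percentile points of the retained replicate breakpoints", {
  cfg <- synthetic_config(n_per_age = 15)
  rec <- simulate_starvation_cohort(cfg, seed = 21)
  est <- bootstrap_critical_weight(rec, n_boot = 200, level = 0.95, seed = 9)
  taus <- attr(est, "boot_age")
  expect_length(taus, 200L - est$n_failed_boot)
  ci <- unname(quantile(taus, c(0.025, 0.975)))
  expect_equal(c(est$age_ci_low, est$age_ci_high), ci, tolerance = 1e-10)
  expect_true(est$age_ci_low <= est$age && est$age <= est$age_ci_high)

  # mass interval is the growth-line image of the replicate breakpoints
  gf <- fit_growth_curve(simulate_growth(cfg, seed = 22))
  est2 <- bootstrap_critical_weight(rec, growth_fit = gf, n_boot = 200, seed = 9)
  expect_equal(c(est2$mass_ci_low, est2$mass_ci_high),
               unname(quantile(gf$intercept + gf$slope * attr(est2, "boot_age"),
                               c(0.025, 0.975))),
               tolerance = 1e-10)
})

test_that("bootstrap is reproducible given a seed and CIs widen with the level", {
  cfg <- synthetic_config(n_per_age = 10)
  rec <- simulate_starvation_cohort(cfg, seed = 4)
  e1 <- bootstrap_critical_weight(rec, n_boot = 100, seed = 77)
  e2 <- bootstrap_critical_weight(rec, n_boot = 100, seed = 77)
  expect_equal(as.data.frame(e1), as.data.frame(e2))
  expect_equal(attr(e1, "boot_age"), attr(e2, "boot_age"))

  e99 <- bootstrap_critical_weight(rec, n_boot = 100, level = 0.99, seed = 77)
  expect_lte(e99$age_ci_low, e1$age_ci_low)
  expect_gte(e99$age_ci_high, e1$age_ci_high)

  # distinct seeds give distinct resampling streams
  e3 <- bootstrap_critical_weight(rec, n_boot = 100, seed = 78)
  expect_false(identical(attr(e1, "boot_age"), attr(e3, "boot_age")))
})

test_that("point-fit failures propagate instead of being bootstrapped over", {
  bad <- data.frame(age = c(0, 2, 4, 0, 2), ttp = c(50, 46, 42, 49, 45))
  expect_error(bootstrap_critical_weight(bad, n_boot = 10, seed = 1),
               class = "cw_degenerate_design_error")
})

test_that("identical groups are exchangeable: zero difference, p of 1", {
  rec <- make_piecewise(tau = 8)
  res <- permute_critical_weight(rec, rec, n_perm = 99, seed = 31)
  expect_equal(res$observed_diff, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1)
})

test_that("the permutation p-value obeys the add-one rule and is seed-stable", {
  cfg_a <- synthetic_config(tau_true = 8, n_per_age = 10)
  cfg_b <- synthetic_config(tau_true = 12, n_per_age = 10)
  a <- simulate_starvation_cohort(cfg_a, group = "a", seed = 1)
  b <- simulate_starvation_cohort(cfg_b, group = "b", seed = 2)
  res <- permute_critical_weight(a, b, n_perm = 199, seed = 5)
  expect_equal(res$p_value, (res$n_as_extreme + 1) / (res$n_perm + 1))
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
  # a 4-hr true separation at this size should be detected
  expect_lt(res$p_value, 0.05)
  expect_equal(res$observed_diff, fit_bisegmental(a)$tau - fit_bisegmental(b)$tau,
               tolerance = 1e-10)

  res2 <- permute_critical_weight(a, b, n_perm = 199, seed = 5)
  expect_identical(res$p_value, res2$p_value)
  expect_identical(res$n_as_extreme, res2$n_as_extreme)
})

test_that("mass-statistic permutation maps each pseudo-group through its growth curve", {
  cfg <- synthetic_config(n_per_age = 10)
  a <- simulate_starvation_cohort(cfg, group = "a", seed = 11)
  b <- simulate_starvation_cohort(cfg, group = "b", seed = 12)
  gfa <- fit_growth_curve(simulate_growth(cfg, group = "a", seed = 13))
  gfb <- fit_growth_curve(simulate_growth(cfg, group = "b", seed = 14))
  res <- permute_critical_weight(a, b, statistic = "mass", n_perm = 99,
                                 seed = 15, growth_fits = list(gfa, gfb))
  expected <- (gfa$intercept + gfa$slope * fit_bisegmental(a)$tau) -
    (gfb$intercept + gfb$slope * fit_bisegmental(b)$tau)
  expect_equal(res$observed_diff, expected, tolerance = 1e-10)
  expect_error(permute_critical_weight(a, b, statistic = "mass", n_perm = 9,
                                       seed = 1),
               class = "cw_config_error")
})
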