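test_that("noise-free piecewise data is recovered exactly", {
  rec <- make_piecewise(tau = 8, b0 = 50, pre = -2, post = 0)
  fit <- fit_bisegmental(rec)
  expect_equal(fit$tau, 8, tolerance = 1e-8)
  b <- coef(fit)
  expect_equal(unname(b[1L]), 50, tolerance = 1e-8)
  expect_equal(unname(b[2L]), -2, tolerance = 1e-8)
  expect_equal(unname(b[2L] + b[3L]), 0, tolerance = 1e-8)
  expect_equal(fit$rss, 0, tolerance = 1e-12)
  expect_true(min(rec$age) <= fit$tau && fit$tau <= max(rec$age))
})

test_that("translation and scale equivariance hold", {
  rec <- make_piecewise(tau = 8)
  fit <- fit_bisegmental(rec)

  shifted <- rec
  shifted$ttp <- shifted$ttp + 10
  fs <- fit_bisegmental(shifted)
  expect_equal(fs$tau, fit$tau)
  expect_equal(unname(coef(fs)[1L]), unname(coef(fit)[1L]) + 10, tolerance = 1e-8)
  expect_equal(unname(coef(fs)[2:3]), unname(coef(fit)[2:3]), tolerance = 1e-8)

  k <- 2
  scaled <- rec
  scaled$age <- scaled$age * k
  fk <- fit_bisegmental(scaled)
  expect_equal(fk$tau, k * fit$tau, tolerance = 1e-6)
  expect_equal(unname(coef(fk)[2:3]), unname(coef(fit)[2:3]) / k, tolerance = 1e-8)
})

test_that("breakpoint recovery on a noisy synthetic cohort matches the dense-grid oracle", {
  cfg <- synthetic_config(tau_true = 9, intercept_true = 47.5, pre_slope = -1.5,
                          post_slope = 0, noise_sd = 2, age_grid = seq(0, 24, 2),
                          n_per_age = 39)   # ~500 larvae
  rec <- simulate_starvation_cohort(cfg, seed = 123)
  expect_equal(nrow(rec), 507L)
  fit <- fit_bisegmental(rec)
  expect_lt(abs(fit$tau - 9), 1.0)

  tau_star <- oracle_tau(rec$age, rec$ttp, step = 0.01)
  expect_lt(abs(fit$tau - tau_star), 0.011)
})

test_that("RSS profile is self-consistent with the fit and exactly reproducible", {
  rec <- make_piecewise(tau = 8)
  taus <- seq(2, 18, 0.5)
  prof <- profile_rss(rec, taus)
  expect_equal(prof$tau, taus)
  zero <- which(prof$rss < 1e-12)
  expect_equal(prof$tau[zero], 8)                # unique zero at the true join
  expect_identical(prof, profile_rss(rec, taus)) # deterministic

  set.seed(7)
  noisy <- rec
  noisy$ttp <- noisy$ttp + rnorm(nrow(noisy), 0, 2)
  fit <- fit_bisegmental(noisy)
  prof <- profile_rss(noisy, taus)
  expect_true(all(fit$rss <= prof$rss[!is.na(prof$rss)] + 1e-9))  # grid optimality
})

test_that("flat profiles tie-break to the smallest age with a warning", {
  rec <- make_piecewise(tau = 8, b0 = 40, pre = 0, post = 0)  # constant response
  expect_warning(fit <- fit_bisegmental(rec), class = "cw_degenerate_fit_warning")
  prof <- suppressWarnings(profile_rss(rec, seq(2, 18, 0.5)))
  admissible <- prof$tau[!is.na(prof$rss)]
  expect_equal(fit$tau, min(admissible))
  expect_true(fit$flat_profile)
})

test_that("degenerate inputs raise typed errors", {
  expect_error(fit_bisegmental(data.frame(age = c(0, 2, 4), ttp = c(5, 4, 3))),
               class = "cw_degenerate_design_error")
  # only 3 distinct ages: no candidate has 2 distinct ages on each side
  expect_error(fit_bisegmental(data.frame(age = rep(c(0, 2, 4), each = 3),
                                          ttp = rnorm(9, 40))),
               class = "cw_no_breakpoint_error")
})

test_that("estimation error shrinks as cohorts grow (n = 50 vs n = 500)", {
  err_for_n <- function(n_per_age, seeds) {
    cfg <- synthetic_config(tau_true = 9, noise_sd = 2, n_per_age = n_per_age)
    vapply(seeds, function(s) {
      rec <- simulate_starvation_cohort(cfg, seed = s)
      abs(fit_bisegmental(rec)$tau - 9)
    }, numeric(1))
  }
  seeds <- 1:200
  expect_lt(median(err_for_n(39, seeds)), median(err_for_n(4, seeds)))
})

test_that("fit methods behave: predict, residuals, simulate, plot, disjoint mode", {
  rec <- make_piecewise(tau = 8)
  fit <- fit_bisegmental(rec)
  expect_equal(predict(fit, 0), unname(coef(fit)[1L]), tolerance = 1e-8)
  expect_equal(predict(fit, data.frame(age = c(8, 20))), c(34, 34),
               tolerance = 1e-8)
  expect_equal(fitted(fit) + residuals(fit), rec$ttp, tolerance = 1e-8)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-8)

  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(dim(sims), c(nrow(rec), 2L))
  expect_equal(sims, simulate(fit, nsim = 2, seed = 5))  # seed-reproducible

  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))

  # disjoint-segments sensitivity mode: without the continuity constraint the
  # zero-RSS split is any cut in (6, 10) here; ties break to the smallest age
  fd <- suppressWarnings(fit_bisegmental(rec, disjoint = TRUE))
  expect_true(fd$tau >= 6 && fd$tau <= 8)
  expect_equal(fd$rss, 0, tolerance = 1e-12)
  expect_equal(unname(coef(fd)[2L]), -2, tolerance = 1e-8)

  # summary carries the scientific quantities
  s <- summary(fit)
  expect_equal(s$post_slope, 0, tolerance = 1e-8)
  expect_output(print(s), "tau")
})
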