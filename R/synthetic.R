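# Synthetic cohorts with the statistical structure the estimator assumes:
# piecewise-linear starvation response with a hinge at the critical-weight
# age, linear larval growth during feeding, and qPCR Ct pairs against a
# stable reference gene. Used for parameter-recovery, coverage and power
# experiments, and to exercise the pipeline with no external data.

#' Configuration of the synthetic cohort generator
#'
#' Collects every parameter of the generative model. Defaults are
#' illustrative, not calibrated to any particular dataset: a breakpoint at
#' 9 hr AL3E with a pre-breakpoint slope of -1.5 hr/hr and a flat plateau
#' near 34 hr (pupariation roughly 32-36 hr after starvation onset once past
#' critical weight), larvae collected every 2 hr from 0 to 24 hr AL3E, and a
#' growth line rising 0.08 mg/hr from 0.8 mg at ecdysis.
#'
#' @param tau_true breakpoint age (hr AL3E); must lie inside the age grid.
#' @param intercept_true expected time to pupariation at age 0 (hr).
#' @param pre_slope slope before the breakpoint (hr/hr, typically negative:
#'   the starvation delay declines as larvae approach critical weight).
#' @param post_slope slope after the breakpoint (hr/hr, ~0: a plateau).
#' @param noise_sd residual SD of time to pupariation (hr), Gaussian
#'   truncated at zero (or lognormal, see `noise`).
#' @param age_grid ages at starvation (hr AL3E), default `seq(0, 24, 2)` —
#'   the 2-hr collection design.
#' @param n_per_age larvae starved per age class.
#' @param growth_intercept,growth_slope,growth_noise_sd the linear growth
#'   line (mg, mg/hr, mg).
#' @param qpcr optional list configuring [simulate_qpcr()]: elements
#'   `times` (default `seq(0, 24, 4)`), `n_replicates` (3), `ref_ct` (16),
#'   `ref_sd` (0.1), `baseline_dct` (named numeric per gene, default 7),
#'   `noise_sd` (0.15, cycles), `fold` (named list of functions of time
#'   giving the fold-change trajectory; default constant 1).
#' @param noise `"gaussian"` (default) truncated-at-zero normal residuals, or
#'   `"lognormal"` for right-skew sensitivity analyses (same mean and SD).
#' @param seed default RNG seed used by the generators when no explicit seed
#'   is passed.
#' @return Object of class `synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(tau_true = 9, noise_sd = 2, n_per_age = 25)
#' cohort <- simulate_starvation_cohort(cfg, group = "sim", seed = 1)
#' fit_bisegmental(cohort)
#' @export
synthetic_config <- function(tau_true = 9, intercept_true = 47.5,
                             pre_slope = -1.5, post_slope = 0,
                             noise_sd = 2, age_grid = seq(0, 24, 2),
                             n_per_age = 25,
                             growth_intercept = 0.8, growth_slope = 0.08,
                             growth_noise_sd = 0.05,
                             qpcr = NULL, noise = c("gaussian", "lognormal"),
                             seed = 1L) {
  noise <- match.arg(noise)
  cfg <- list(tau_true = tau_true, intercept_true = intercept_true,
              pre_slope = pre_slope, post_slope = post_slope,
              noise_sd = noise_sd, age_grid = sort(unique(age_grid)),
              n_per_age = as.integer(n_per_age),
              growth_intercept = growth_intercept, growth_slope = growth_slope,
              growth_noise_sd = growth_noise_sd,
              qpcr = qpcr, noise = noise, seed = as.integer(seed))
  if (cfg$noise_sd < 0 || cfg$growth_noise_sd < 0)
    stop_cw("noise SDs must be non-negative", "cw_config_error")
  if (cfg$n_per_age < 1L)
    stop_cw("n_per_age must be at least 1", "cw_config_error")
  if (tau_true < min(cfg$age_grid) || tau_true > max(cfg$age_grid))
    stop_cw("tau_true must lie within the age grid's span", "cw_config_error")
  mu <- starvation_mean(cfg, cfg$age_grid)
  if (any(mu <= 0))
    stop_cw("expected time to pupariation is non-positive at some grid age (biologically impossible mean)",
            "cw_config_error")
  class(cfg) <- "synthetic_config"
  cfg
}

starvation_mean <- function(config, age) {
  config$intercept_true + config$pre_slope * age +
    (config$post_slope - config$pre_slope) * pmax(0, age - config$tau_true)
}

draw_noisy <- function(n, mean, sd, noise) {
  if (noise == "lognormal") {
    if (sd == 0) return(rep(mean, length.out = n))
    # match mean and SD of the target on the original scale
    s2 <- log(1 + (sd / mean)^2)
    stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
  } else {
    rnorm_trunc(n, mean, sd, lower = 0)
  }
}

#' Simulate a starvation-response cohort
#'
#' For each age on the grid, `n_per_age` larvae with expected time to
#' pupariation following the configured hinge and Gaussian (truncated at
#' zero) or lognormal noise.
#'
#' @param config a [synthetic_config()].
#' @param group group label to stamp on the records.
#' @param seed RNG seed; defaults to `config$seed`. The caller's RNG stream
#'   is left untouched.
#' @return starvation records as accepted by [fit_bisegmental()]:
#'   columns `larva_id`, `group`, `age`, `ttp`, `pupariated` (all `TRUE`).
#' @export
simulate_starvation_cohort <- function(config, group = "synthetic",
                                       seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  res <- with_seed(seed, {
    age <- rep(config$age_grid, each = config$n_per_age)
    mu <- starvation_mean(config, age)
    ttp <- if (config$noise == "lognormal")
      draw_noisy(length(age), mu, config$noise_sd, "lognormal")
    else
      rnorm_trunc(length(age), mu, config$noise_sd)
    data.frame(larva_id = paste0(group, "_", seq_along(age)),
               group = group, age = age, ttp = ttp, pupariated = TRUE,
               stringsAsFactors = FALSE)
  })
  attr(res, "seed_used") <- NULL
  res
}

#' Simulate a larval growth table
#'
#' Linear growth during feeding: mass = intercept + slope * age plus
#' Gaussian noise truncated at zero, `n_per_age` larvae weighed per grid age.
#'
#' @inheritParams simulate_starvation_cohort
#' @return growth records as accepted by [fit_growth_curve()].
#' @export
simulate_growth <- function(config, group = "synthetic", seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  res <- with_seed(seed, {
    age <- rep(config$age_grid, each = config$n_per_age)
    mu <- config$growth_intercept + config$growth_slope * age
    if (any(mu <= 0))
      stop_cw("expected mass non-positive at some grid age", "cw_config_error")
    mass <- rnorm_trunc(length(age), mu, config$growth_noise_sd)
    data.frame(larva_id = paste0(group, "_g", seq_along(age)),
               group = group, age = age, mass = mass,
               stringsAsFactors = FALSE)
  })
  attr(res, "seed_used") <- NULL
  res
}

#' Simulate a qPCR Ct table
#'
#' Reference-gene Ct stable around a constant; target Ct equals the reference
#' plus a per-gene baseline \eqn{\Delta Ct} minus \eqn{\log_2} of the
#' configured fold-change trajectory, plus measurement noise. With the
#' default trajectory (constant 1), [relative_expression()] recovers values
#' near 1 at all times.
#'
#' @inheritParams simulate_starvation_cohort
#' @param genes character vector of gene names to simulate.
#' @return Ct records as accepted by [relative_expression()].
#' @export
simulate_qpcr <- function(config, genes = "phm", group = "synthetic",
                          seed = config$seed) {
  stopifnot(inherits(config, "synthetic_config"))
  q <- config$qpcr %||% list()
  times <- q$times %||% seq(0, 24, 4)
  n_rep <- q$n_replicates %||% 3L
  ref_ct <- q$ref_ct %||% 16
  ref_sd <- q$ref_sd %||% 0.1
  noise_sd <- q$noise_sd %||% 0.15
  baseline <- q$baseline_dct %||% setNames(rep(7, length(genes)), genes)
  folds <- q$fold %||% setNames(rep(list(function(t) rep(1, length(t))), length(genes)), genes)

  res <- with_seed(seed, {
    rows <- list()
    for (g in genes) {
      base_g <- if (g %in% names(baseline)) baseline[[g]] else 7
      fold_g <- if (g %in% names(folds)) folds[[g]] else function(t) rep(1, length(t))
      for (tm in times) {
        ref <- rnorm(n_rep, ref_ct, ref_sd)
        tgt <- ref + base_g - log2(fold_g(tm)) + rnorm(n_rep, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, group = group, time = tm, replicate = seq_len(n_rep),
          ct_target = tgt, ct_reference = ref, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
  attr(res, "seed_used") <- NULL
  rownames(res) <- NULL
  res
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  starvation: tau* = %g hr, mean = %g %+g*age, plateau slope %g, noise SD %g (%s)\n",
              x$tau_true, x$intercept_true, x$pre_slope, x$post_slope,
              x$noise_sd, x$noise))
  cat(sprintf("  design: ages %g-%g hr every %g hr, %d larvae per age\n",
              min(x$age_grid), max(x$age_grid),
              if (length(x$age_grid) > 1) x$age_grid[2L] - x$age_grid[1L] else 0,
              x$n_per_age))
  cat(sprintf("  growth: mass = %g + %g*age mg, noise SD %g\n",
              x$growth_intercept, x$growth_slope, x$growth_noise_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
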