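# Case-bootstrap confidence intervals for age and mass at critical weight,
# and permutation tests comparing the estimate between two groups.
#
# The resampling unit is the larva. Because ages at starvation are fixed by
# the experimenter (the 2-hr collection design), larvae are by default
# resampled with replacement *within* each age class, which preserves the
# design's age coverage; an unstratified case bootstrap is available via
# `stratified = FALSE`.

new_cw_estimate <- function(fields) {
  est <- list(
    group = fields$group %||% NA_character_,
    age = as.numeric(fields$age),
    age_ci_low = as.numeric(fields$age_ci_low),
    age_ci_high = as.numeric(fields$age_ci_high),
    mass = as.numeric(fields$mass %||% NA_real_),
    mass_ci_low = as.numeric(fields$mass_ci_low %||% NA_real_),
    mass_ci_high = as.numeric(fields$mass_ci_high %||% NA_real_),
    n_boot = as.integer(fields$n_boot),
    n_failed_boot = as.integer(fields$n_failed_boot),
    level = as.numeric(fields$level %||% 0.95),
    seed = as.integer(fields$seed)
  )
  if (est$n_failed_boot > est$n_boot)
    stop_cw("n_failed_boot exceeds n_boot", "cw_validation_error")
  if (is.finite(est$age) &&
      (est$age_ci_low > est$age || est$age > est$age_ci_high))
    stop_cw("age CI does not bracket the point estimate", "cw_validation_error")
  if (is.finite(est$mass) &&
      (est$mass_ci_low > est$mass || est$mass > est$mass_ci_high))
    stop_cw("mass CI does not bracket the point estimate", "cw_validation_error")
  structure(est, class = "critical_weight_estimate")
}

clean_starvation_xy <- function(records) {
  records <- as.data.frame(records)
  stopifnot(all(c("age", "ttp") %in% names(records)))
  if ("pupariated" %in% names(records))
    records <- records[records$pupariated, , drop = FALSE]
  keep <- is.finite(records$age) & is.finite(records$ttp)
  records <- records[keep, , drop = FALSE]
  g <- if ("group" %in% names(records)) unique(as.character(records$group)) else character()
  list(x = as.numeric(records$age), y = as.numeric(records$ttp),
       group = if (length(g) == 1L) g else NULL)
}

strata_indices <- function(x, stratified) {
  if (stratified) split(seq_along(x), x) else list(seq_along(x))
}

#' Bootstrap confidence intervals for age and mass at critical weight
#'
#' Case bootstrap of the hinge-regression breakpoint: larvae are resampled
#' with replacement (within age class by default), the bi-segmental model is
#' refit to each replicate dataset, and percentile intervals at `level` are
#' taken over the replicate breakpoints. The mass at critical weight and its
#' interval are obtained by mapping the point estimate and every replicate
#' breakpoint through the group's linear growth curve; by default the growth
#' fit is held fixed across replicates, with joint resampling of the growth
#' data available via `resample_growth = TRUE`.
#'
#' Replicates where the refit fails (e.g. a degenerate resampled design) are
#' excluded and counted in `n_failed_boot`; more than 20% failures aborts
#' with an unstable-estimate error.
#'
#' @param records starvation records as in [fit_bisegmental()].
#' @param growth_fit optional [fit_growth_curve()] result used to convert
#'   breakpoint ages to masses; when `NULL` the mass fields are `NA`.
#' @param n_boot number of bootstrap datasets (the study's convention: 1000).
#' @param level confidence level of the percentile interval (default 0.95).
#' @param seed integer seed; the whole resampling stream is reproducible given
#'   it. `NULL` draws (and records) a seed from the session RNG.
#' @param stratified resample within age classes (default) or over all larvae.
#' @param resample_growth also re-fit the growth curve on a case-resample of
#'   `growth_records` in each replicate (joint resampling).
#' @param growth_records growth table; required when `resample_growth = TRUE`.
#' @param grid_step,refine_tol passed to the hinge fit.
#' @return A `critical_weight_estimate`: age and mass at critical weight with
#'   their CIs, `n_boot`, `n_failed_boot`, `level`, `seed`, `group`.
#' @examples
#' cfg <- synthetic_config(noise_sd = 0)
#' cohort <- simulate_starvation_cohort(cfg, group = "demo")
#' est <- bootstrap_critical_weight(cohort, n_boot = 50, seed = 1)
#' est$age                    # recovers the configured breakpoint exactly
#' c(est$age_ci_low, est$age_ci_high)
#' @export
bootstrap_critical_weight <- function(records, growth_fit = NULL, n_boot = 1000,
                                      level = 0.95, seed = NULL,
                                      stratified = TRUE,
                                      resample_growth = FALSE,
                                      growth_records = NULL,
                                      grid_step = 0.5, refine_tol = 0.01) {
  stopifnot(n_boot >= 1, level > 0, level < 1)
  dat <- clean_starvation_xy(records)
  point <- fit_biseg_xy(dat$x, dat$y, grid_step, refine_tol)  # errors propagate
  if (resample_growth && is.null(growth_records))
    stop_cw("resample_growth = TRUE requires growth_records", "cw_config_error")

  strata <- strata_indices(dat$x, stratified)
  res <- with_seed(seed, {
    taus <- rep(NA_real_, n_boot)
    masses <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(strata, function(s)
        s[sample.int(length(s), length(s), replace = TRUE)]), use.names = FALSE)
      fb <- tryCatch(
        fit_biseg_xy(dat$x[idx], dat$y[idx], grid_step, refine_tol,
                     warn_ties = FALSE),
        critweight_error = function(e) NULL)
      if (is.null(fb)) next
      taus[b] <- fb$tau
      if (!is.null(growth_fit)) {
        gf <- growth_fit
        if (resample_growth) {
          gi <- sample.int(nrow(growth_records), nrow(growth_records), replace = TRUE)
          gf <- tryCatch(fit_growth_curve(growth_records[gi, , drop = FALSE]),
                         critweight_error = function(e) NULL)
        }
        if (!is.null(gf))
          masses[b] <- gf$intercept + gf$slope * fb$tau
      }
    }
    list(taus = taus, masses = masses)
  })
  seed_used <- attr(res, "seed_used")

  taus <- res$taus
  n_failed <- sum(is.na(taus))
  if (n_failed > 0.2 * n_boot)
    stop_cw(sprintf("unstable estimate: %d of %d bootstrap refits failed",
                    n_failed, n_boot), "cw_unstable_error")
  kept <- taus[!is.na(taus)]
  alpha <- (1 - level) / 2
  ci <- quantile(kept, c(alpha, 1 - alpha), names = FALSE)

  mass <- mass_ci <- c(NA_real_, NA_real_)
  mass_pt <- NA_real_
  if (!is.null(growth_fit)) {
    mass_pt <- age_to_mass(growth_fit, point$tau,
                           group = dat$group,
                           allow_cross_group = is.null(dat$group))
    mkept <- res$masses[!is.na(res$masses)]
    mass_ci <- quantile(mkept, c(alpha, 1 - alpha), names = FALSE)
  }

  est <- new_cw_estimate(list(
    group = dat$group,
    age = point$tau,
    # percentile endpoints, expanded (rarely needed) to bracket the point fit
    age_ci_low = min(ci[1L], point$tau),
    age_ci_high = max(ci[2L], point$tau),
    mass = mass_pt,
    mass_ci_low = if (is.finite(mass_pt)) min(mass_ci[1L], mass_pt) else NA_real_,
    mass_ci_high = if (is.finite(mass_pt)) max(mass_ci[2L], mass_pt) else NA_real_,
    n_boot = n_boot, n_failed_boot = n_failed,
    level = level, seed = seed_used
  ))
  # retained replicate values, for diagnostics (percentile checks, histograms)
  attr(est, "boot_age") <- kept
  if (!is.null(growth_fit)) attr(est, "boot_mass") <- res$masses[!is.na(res$masses)]
  est
}

#' Permutation test for a difference in critical weight between two groups
#'
#' Two-sided test of the null that the groups share the same age (or mass) at
#' critical weight. Larvae from both groups are pooled and group labels are
#' randomly re-assigned — within matched age classes by default, preserving
#' each group's size per class — both cohorts are refit, and the difference in
#' the chosen statistic is recorded. The p-value uses the add-one rule
#' \eqn{p = (n_{as\,extreme} + 1)/(n_{perm} + 1)} on absolute differences, so
#' it is never exactly zero.
#'
#' @param records_a,records_b starvation records for the two groups.
#' @param statistic `"age"` (breakpoint, hr) or `"mass"` (breakpoint mapped
#'   through each group's growth curve, mg).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed; `NULL` draws and records one.
#' @param growth_fits list of two `growth_fit` objects (for group a and b);
#'   required for `statistic = "mass"`. Each permuted pseudo-group is mapped
#'   through the growth curve of the label it carries.
#' @param stratified permute labels within matched age classes (default) or
#'   over the whole pool.
#' @param grid_step,refine_tol passed to the hinge fit.
#' @return A `permutation_result`: `observed_diff` (a minus b), `n_perm`
#'   (retained permutations), `n_as_extreme`, `p_value`, `statistic`, `seed`.
#'   Permutations whose refit fails are discarded and counted
#'   (`n_discarded`); more than 20% discards aborts.
#' @examples
#' cfg <- synthetic_config(n_per_age = 10)
#' a <- simulate_starvation_cohort(cfg, group = "a", seed = 1)
#' b <- simulate_starvation_cohort(cfg, group = "b", seed = 2)
#' permute_critical_weight(a, b, n_perm = 99, seed = 3)
#' @export
permute_critical_weight <- function(records_a, records_b,
                                    statistic = c("age", "mass"),
                                    n_perm = 1000, seed = NULL,
                                    growth_fits = NULL, stratified = TRUE,
                                    grid_step = 0.5, refine_tol = 0.01) {
  statistic <- match.arg(statistic)
  a <- clean_starvation_xy(records_a)
  b <- clean_starvation_xy(records_b)
  if (statistic == "mass") {
    if (!is.list(growth_fits) || length(growth_fits) != 2L ||
        !all(vapply(growth_fits, inherits, logical(1), "growth_fit")))
      stop_cw("statistic = 'mass' requires growth_fits = list(<fit a>, <fit b>)",
              "cw_config_error")
  }
  stat_of <- function(tau, which_group) {
    if (statistic == "age") tau
    else growth_fits[[which_group]]$intercept + growth_fits[[which_group]]$slope * tau
  }

  fa <- fit_biseg_xy(a$x, a$y, grid_step, refine_tol, warn_ties = FALSE)
  fb <- fit_biseg_xy(b$x, b$y, grid_step, refine_tol, warn_ties = FALSE)
  observed <- stat_of(fa$tau, 1L) - stat_of(fb$tau, 2L)

  x <- c(a$x, b$x)
  y <- c(a$y, b$y)
  lab <- rep(c(1L, 2L), c(length(a$x), length(b$x)))
  strata <- strata_indices(x, stratified)

  res <- with_seed(seed, {
    diffs <- rep(NA_real_, n_perm)
    for (p in seq_len(n_perm)) {
      pl <- lab
      for (s in strata) pl[s] <- pl[s][sample.int(length(s))]
      da <- tryCatch(fit_biseg_xy(x[pl == 1L], y[pl == 1L], grid_step,
                                  refine_tol, warn_ties = FALSE),
                     critweight_error = function(e) NULL)
      db <- tryCatch(fit_biseg_xy(x[pl == 2L], y[pl == 2L], grid_step,
                                  refine_tol, warn_ties = FALSE),
                     critweight_error = function(e) NULL)
      if (is.null(da) || is.null(db)) next
      diffs[p] <- stat_of(da$tau, 1L) - stat_of(db$tau, 2L)
    }
    diffs
  })
  seed_used <- attr(res, "seed_used")
  n_discarded <- sum(is.na(res))
  if (n_discarded > 0.2 * n_perm)
    stop_cw(sprintf("unstable test: %d of %d permutation refits failed",
                    n_discarded, n_perm), "cw_unstable_error")
  kept <- res[!is.na(res)]
  n_extreme <- sum(abs(kept) >= abs(observed) - 1e-12)

  structure(list(
    observed_diff = observed,
    statistic = statistic,
    n_perm = length(kept),
    n_discarded = n_discarded,
    n_as_extreme = n_extreme,
    p_value = (n_extreme + 1) / (length(kept) + 1),
    group_a = a$group, group_b = b$group,
    seed = seed_used
  ), class = "permutation_result")
}

#' @export
print.critical_weight_estimate <- function(x, ...) {
  cat("Critical weight estimate",
      if (!is.na(x$group)) paste0("[", x$group, "]"), "\n")
  cat(sprintf("  age : %.2f hr AL3E  (%d%% CI %.2f - %.2f)\n",
              x$age, round(100 * x$level), x$age_ci_low, x$age_ci_high))
  if (is.finite(x$mass))
    cat(sprintf("  mass: %.3f mg       (%d%% CI %.3f - %.3f)\n",
                x$mass, round(100 * x$level), x$mass_ci_low, x$mass_ci_high))
  cat(sprintf("  %d bootstrap datasets (%d failed refits), seed %d\n",
              x$n_boot, x$n_failed_boot, x$seed))
  invisible(x)
}

#' @export
as.data.frame.critical_weight_estimate <- function(x, ...) {
  data.frame(group = x$group, age = x$age,
             age_ci_low = x$age_ci_low, age_ci_high = x$age_ci_high,
             mass = x$mass, mass_ci_low = x$mass_ci_low,
             mass_ci_high = x$mass_ci_high,
             n_boot = x$n_boot, n_failed_boot = x$n_failed_boot,
             level = x$level, seed = x$seed,
             stringsAsFactors = FALSE)
}

#' @export
print.permutation_result <- function(x, ...) {
  unit <- if (x$statistic == "age") "hr" else "mg"
  cat(sprintf("Permutation test on %s at critical weight (%s vs %s)\n",
              x$statistic, x$group_a %||% "a", x$group_b %||% "b"))
  cat(sprintf("  observed difference: %.3f %s\n", x$observed_diff, unit))
  cat(sprintf("  p = %.4g  (%d of %d permutations as extreme, add-one rule; seed %d)\n",
              x$p_value, x$n_as_extreme, x$n_perm, x$seed))
  if (x$n_discarded > 0)
    cat(sprintf("  %d permutation(s) discarded (failed refits)\n", x$n_discarded))
  invisible(x)
}
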