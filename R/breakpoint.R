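# Hinge (bi-segmental) regression of time-to-pupariation on age at starvation.
#
# Model: ttp = beta0 + beta1 * age + beta2 * max(0, age - tau) + eps.
# tau, the join of the two segments, is the age at critical weight. For each
# candidate tau the three linear coefficients are the OLS solution; tau is
# chosen to minimise the residual sum of squares over a dense candidate
# lattice between the 2nd-smallest and 2nd-largest observed ages.

# Closed-form OLS profile of RSS over breakpoint candidates, vectorised via
# suffix sums. A candidate is admissible only when at least two distinct ages
# lie on each of its sides (otherwise the hinge can chase single points at the
# design's edge). Returns rss = Inf for inadmissible or rank-deficient taus.
hinge_profile <- function(x, y, taus) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  cx <- c(0, cumsum(xs))
  cxx <- c(0, cumsum(xs * xs))
  cy <- c(0, cumsum(ys))
  cxy <- c(0, cumsum(xs * ys))
  Sx <- cx[n + 1L]; Sxx <- cxx[n + 1L]; Sy <- cy[n + 1L]; Sxy <- cxy[n + 1L]
  Syy <- sum(ys * ys)

  idx <- findInterval(taus, xs)          # points with age <= tau
  nR <- n - idx
  SxR <- Sx - cx[idx + 1L]
  SxxR <- Sxx - cxx[idx + 1L]
  SyR <- Sy - cy[idx + 1L]
  SxyR <- Sxy - cxy[idx + 1L]

  Sh <- SxR - taus * nR
  Shh <- SxxR - 2 * taus * SxR + taus^2 * nR
  Sxh <- SxxR - taus * SxR
  Shy <- SxyR - taus * SyR

  a <- n; b <- Sx; cc <- Sh
  d <- Sxx; e <- Sxh; f <- Shh
  A11 <- d * f - e * e
  A12 <- cc * e - b * f
  A13 <- b * e - cc * d
  A22 <- a * f - cc * cc
  A23 <- b * cc - a * e
  A33 <- a * d - b * b
  det <- a * A11 + b * A12 + cc * A13

  p <- Sy; q <- Sxy; r <- Shy
  beta0 <- (A11 * p + A12 * q + A13 * r) / det
  beta1 <- (A12 * p + A22 * q + A23 * r) / det
  beta2 <- (A13 * p + A23 * q + A33 * r) / det
  rss <- pmax(Syy - (beta0 * p + beta1 * q + beta2 * r), 0)

  ux <- unique(xs)                       # sorted; admissibility by distinct ages
  iu <- findInterval(taus, ux)
  ok <- iu >= 2L & (length(ux) - iu) >= 2L &
    is.finite(det) & abs(det) > 1e-10 * (abs(a * d * f) + 1)
  rss[!ok] <- Inf
  beta0[!ok] <- beta1[!ok] <- beta2[!ok] <- NA_real_
  list(tau = taus, rss = rss, beta0 = beta0, beta1 = beta1, beta2 = beta2,
       admissible = ok)
}

# Default coarse candidates: every grid_step between the 2nd-smallest and
# 2nd-largest observed age (the observed design is typically a 2-hr grid),
# plus the interior observed ages themselves. The RSS profile is continuous
# in tau and smooth between consecutive data ages, so with the data ages as
# candidates every basin of the profile has a candidate-local minimum on its
# boundary or inside it — local refinement around each local minimum then
# provably reaches the global basin.
default_candidates <- function(x, grid_step) {
  ux <- sort(unique(x))
  if (length(ux) < 4L)
    stop_cw("need at least 4 distinct ages to search for a breakpoint",
            "cw_no_breakpoint_error")
  lo <- ux[2L]
  hi <- ux[length(ux) - 1L]
  taus <- seq(lo, hi, by = grid_step)
  sort(unique(c(taus, ux[ux >= lo & ux <= hi])))
}

# Lean fitting path shared with the resampling module: numeric vectors in,
# list(tau, rss, beta) out. Tie-breaking is deterministic (smallest tau);
# `warn_ties` controls whether a tie is surfaced to the user.
#
# The search evaluates the closed-form RSS profile on a dense lattice at
# refine_tol resolution spanning the whole candidate range (coarse grid_step
# candidates and interior observed ages included). A two-stage search that
# refines only around the best coarse candidate can miss the global basin:
# with irregular ages the profile develops minima narrower than the coarse
# spacing whose flanks slope towards other basins. The vectorised profile
# makes the exhaustive scan as cheap as the two-stage one, and exact to the
# stated resolution by construction.
fit_biseg_xy <- function(x, y, grid_step = 0.5, refine_tol = 0.01,
                         candidates = NULL, warn_ties = TRUE) {
  if (length(x) < 6L)
    stop_cw("need at least 6 records to fit a bi-segmental regression",
            "cw_degenerate_design_error")
  if (is.null(candidates)) {
    coarse <- default_candidates(x, grid_step)
    taus <- sort(unique(c(coarse,
                          seq(coarse[1L], coarse[length(coarse)],
                              by = refine_tol))))
  } else {
    taus <- sort(unique(as.numeric(candidates)))
  }
  prof <- hinge_profile(x, y, taus)
  if (!any(prof$admissible))
    stop_cw("no admissible breakpoint candidate with >= 2 distinct ages on each side",
            "cw_no_breakpoint_error")
  rmin <- min(prof$rss)
  tied <- which(prof$rss <= rmin + 1e-9 * (1 + rmin))
  k <- tied[1L]
  flat <- length(tied) > 1L
  if (flat && warn_ties)
    warn_cw("RSS profile has tied minima; breakpoint tie broken to smallest age",
            "cw_degenerate_fit_warning")
  tau <- taus[k]

  # final coefficients via QR for numerical hygiene
  X <- cbind(1, x, pmax(0, x - tau))
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  rss <- sum(fit$residuals^2)
  list(tau = tau, beta0 = beta[1L], beta1 = beta[2L], beta2 = beta[3L],
       rss = rss, n = length(x), flat = flat,
       fitted = drop(X %*% beta), residuals = y - drop(X %*% beta))
}

#' Fit a bi-segmental (hinge) regression of time to pupariation on age at starvation
#'
#' Estimates the age at critical weight as the breakpoint of a continuous
#' two-segment linear model
#' \deqn{E[t] = \beta_0 + \beta_1 a + \beta_2 \max(0, a - \tau),}
#' where \eqn{t} is time to pupariation (hr from starvation onset) and \eqn{a}
#' is age at starvation (hr AL3E). For every candidate \eqn{\tau} the linear
#' coefficients are the exact OLS solution; the returned \eqn{\tau} minimises
#' the residual sum of squares over a dense candidate lattice at resolution
#' `refine_tol` spanning the default grid (every `grid_step` hours between
#' the 2nd-smallest and 2nd-largest observed age, interior observed ages
#' included). The scan is exhaustive rather than two-stage because with
#' irregular designs the RSS profile can hold minima narrower than any
#' coarse spacing; the closed-form profile makes this exact search cheap.
#' The fit is deterministic: ties in RSS are broken to the smallest
#' \eqn{\tau}, with a warning.
#'
#' Larvae that died before pupariation (`pupariated == FALSE`) are excluded
#' from the fit and counted in the result; time to pupariation is undefined
#' for them. Neither slope is constrained: after critical weight the second
#' segment is typically flat, but cohorts fed 20-hydroxyecdysone can show a
#' *negative* post-breakpoint slope, so the model leaves it free.
#'
#' @param records data frame of starvation records with numeric columns `age`
#'   (hr AL3E) and `ttp` (hr from starvation onset to pupariation), optionally
#'   a logical `pupariated` column and a `group` label column; typically from
#'   [read_starvation_table()] or [simulate_starvation_cohort()].
#' @param grid_step coarse candidate spacing in hours (default 0.5, against
#'   the study's 2-hr collection grid).
#' @param refine_tol resolution of the local refinement, hours (default 0.01).
#' @param candidates optional explicit vector of candidate breakpoints,
#'   overriding the default grid (2nd-smallest to 2nd-largest observed age).
#' @param disjoint if `TRUE`, fit two independent lines split at each candidate
#'   instead of a continuous hinge (sensitivity analysis; the continuous hinge
#'   is the estimator proper because it makes the inflection point
#'   well-defined).
#' @param group optional group label stored in the fit; defaults to the
#'   records' single group label when present.
#'
#' @return An object of class `"biseg_fit"`: a list with elements
#'   `coefficients` (named: intercept, pre-breakpoint slope, slope change),
#'   `tau` (breakpoint age, hr AL3E), `rss`, `sigma` (residual SD), `n`,
#'   `n_excluded`, `group`, `model` (the fitted data), and the search settings.
#'   Methods: `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `plot`, `simulate`.
#'
#' @examples
#' ages <- rep(seq(0, 20, 2), each = 3)
#' ttp <- ifelse(ages <= 8, 50 - 2 * ages, 34)
#' fit <- fit_bisegmental(data.frame(age = ages, ttp = ttp))
#' fit$tau        # 8
#' coef(fit)
#' @seealso [profile_rss()], [bootstrap_critical_weight()], [age_to_mass()]
#' @export
fit_bisegmental <- function(records, grid_step = 0.5, refine_tol = 0.01,
                            candidates = NULL, disjoint = FALSE, group = NULL) {
  records <- as.data.frame(records)
  stopifnot(all(c("age", "ttp") %in% names(records)))
  n_excluded <- 0L
  if ("pupariated" %in% names(records)) {
    n_excluded <- sum(!records$pupariated)
    records <- records[records$pupariated, , drop = FALSE]
  }
  x <- as.numeric(records$age)
  y <- as.numeric(records$ttp)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (is.null(group) && "group" %in% names(records)) {
    g <- unique(as.character(records$group))
    if (length(g) == 1L) group <- g
  }

  core <- if (disjoint) {
    fit_disjoint_xy(x, y, grid_step = grid_step, refine_tol = refine_tol,
                    candidates = candidates)
  } else {
    fit_biseg_xy(x, y, grid_step = grid_step, refine_tol = refine_tol,
                 candidates = candidates)
  }

  structure(list(
    coefficients = c("(Intercept)" = unname(core$beta0),
                     "age" = unname(core$beta1),
                     "hinge(age-tau)" = unname(core$beta2)),
    tau = core$tau,
    rss = core$rss,
    sigma = if (core$n > 4) sqrt(core$rss / (core$n - 4)) else NA_real_,
    n = core$n,
    n_excluded = n_excluded,
    group = group,
    model = data.frame(age = x, ttp = y),
    fitted.values = core$fitted,
    residuals = core$residuals,
    flat_profile = core$flat,
    disjoint = disjoint,
    grid = list(step = grid_step, refine_tol = refine_tol,
                candidates = candidates),
    call = match.call()
  ), class = "biseg_fit")
}

# Disjoint-segments variant: two unconnected OLS lines split at tau.
fit_disjoint_xy <- function(x, y, grid_step = 0.5, refine_tol = 0.01,
                            candidates = NULL) {
  if (length(x) < 6L)
    stop_cw("need at least 6 records to fit a bi-segmental regression",
            "cw_degenerate_design_error")
  taus <- candidates %||% default_candidates(x, grid_step)
  ux <- sort(unique(x))
  rss_at <- function(tau) {
    iu <- findInterval(tau, ux)
    if (iu < 2L || (length(ux) - iu) < 2L) return(Inf)
    l <- x <= tau
    fl <- lm.fit(cbind(1, x[l]), y[l])
    fr <- lm.fit(cbind(1, x[!l]), y[!l])
    sum(fl$residuals^2) + sum(fr$residuals^2)
  }
  rss <- vapply(taus, rss_at, numeric(1))
  if (!any(is.finite(rss)))
    stop_cw("no admissible breakpoint candidate with >= 2 distinct ages on each side",
            "cw_no_breakpoint_error")
  rmin <- min(rss)
  tied <- which(rss <= rmin + 1e-9 * (1 + rmin))
  k <- tied[1L]
  if (length(tied) > 1L)
    warn_cw("RSS profile has tied minima; breakpoint tie broken to smallest age",
            "cw_degenerate_fit_warning")
  fine <- seq(taus[max(1L, k - 1L)], taus[min(length(taus), k + 1L)],
              by = refine_tol)
  rf <- vapply(fine, rss_at, numeric(1))
  tau <- fine[which.min(rf)]
  l <- x <= tau
  fl <- lm.fit(cbind(1, x[l]), y[l])
  fr <- lm.fit(cbind(1, x[!l]), y[!l])
  fitted <- numeric(length(x))
  fitted[l] <- fl$fitted.values
  fitted[!l] <- fr$fitted.values
  list(tau = tau,
       beta0 = fl$coefficients[1L], beta1 = fl$coefficients[2L],
       beta2 = fr$coefficients[2L] - fl$coefficients[2L],
       rss = sum(fl$residuals^2) + sum(fr$residuals^2),
       n = length(x), flat = length(tied) > 1L,
       fitted = fitted, residuals = y - fitted)
}

#' RSS profile of the hinge model over candidate breakpoints
#'
#' Diagnostic companion to [fit_bisegmental()]: the residual sum of squares of
#' the OLS hinge fit at each supplied candidate breakpoint. Candidates without
#' at least two distinct ages on each side are inadmissible and get `NA`.
#'
#' @param records as in [fit_bisegmental()].
#' @param taus numeric vector of candidate breakpoint ages (hr AL3E).
#' @return data frame with columns `tau` and `rss` (`NA` where inadmissible).
#' @examples
#' ages <- rep(seq(0, 20, 2), each = 2)
#' ttp <- ifelse(ages <= 8, 50 - 2 * ages, 34)
#' prof <- profile_rss(data.frame(age = ages, ttp = ttp), seq(4, 16, 0.5))
#' prof$tau[which.min(prof$rss)]  # 8
#' @export
profile_rss <- function(records, taus) {
  records <- as.data.frame(records)
  stopifnot(all(c("age", "ttp") %in% names(records)))
  if ("pupariated" %in% names(records))
    records <- records[records$pupariated, , drop = FALSE]
  prof <- hinge_profile(as.numeric(records$age), as.numeric(records$ttp),
                        as.numeric(taus))
  data.frame(tau = prof$tau,
             rss = ifelse(prof$admissible, prof$rss, NA_real_))
}

#' @export
print.biseg_fit <- function(x, digits = max(3L, getOption("digits") - 3L), ...) {
  cat("Bi-segmental (hinge) regression",
      if (!is.null(x$group)) paste0("[", x$group, "]"), "\n")
  cat(sprintf("  breakpoint (age at critical weight): %.*f hr AL3E\n",
              2L, x$tau))
  cat(sprintf("  pre-breakpoint slope: %s hr/hr, post-breakpoint slope: %s hr/hr\n",
              format(x$coefficients[2L], digits = digits),
              format(x$coefficients[2L] + x$coefficients[3L], digits = digits)))
  cat(sprintf("  n = %d (excluded non-pupariating: %d), RSS = %s\n",
              x$n, x$n_excluded, format(x$rss, digits = digits)))
  invisible(x)
}

#' @export
summary.biseg_fit <- function(object, ...) {
  out <- list(
    tau = object$tau,
    coefficients = object$coefficients,
    pre_slope = unname(object$coefficients[2L]),
    post_slope = unname(object$coefficients[2L] + object$coefficients[3L]),
    rss = object$rss,
    sigma = object$sigma,
    n = object$n,
    n_excluded = object$n_excluded,
    group = object$group,
    flat_profile = object$flat_profile
  )
  class(out) <- "summary.biseg_fit"
  out
}

#' @export
print.summary.biseg_fit <- function(x, ...) {
  cat("Bi-segmental regression summary",
      if (!is.null(x$group)) paste0("[", x$group, "]"), "\n")
  cat(sprintf("  tau (breakpoint) : %.3f hr AL3E\n", x$tau))
  cat(sprintf("  intercept        : %.3f hr\n", x$coefficients[1L]))
  cat(sprintf("  pre-slope        : %.3f hr/hr\n", x$pre_slope))
  cat(sprintf("  post-slope       : %.3f hr/hr\n", x$post_slope))
  cat(sprintf("  residual SD      : %s hr on %d larvae (%d excluded)\n",
              format(x$sigma, digits = 4), x$n, x$n_excluded))
  if (x$flat_profile)
    cat("  note: flat RSS profile; breakpoint tie broken to smallest age\n")
  invisible(x)
}

#' @export
coef.biseg_fit <- function(object, ...) object$coefficients

#' Predicted time to pupariation from a hinge fit
#'
#' @param object a `biseg_fit`.
#' @param newdata data frame with an `age` column, or a numeric vector of ages
#'   (hr AL3E). Defaults to the fitted data.
#' @param ... unused.
#' @return numeric vector of expected times to pupariation (hr).
#' @export
predict.biseg_fit <- function(object, newdata = NULL, ...) {
  age <- if (is.null(newdata)) object$model$age
         else if (is.data.frame(newdata)) as.numeric(newdata$age)
         else as.numeric(newdata)
  b <- object$coefficients
  drop(cbind(1, age, pmax(0, age - object$tau)) %*% b)
}

#' @export
fitted.biseg_fit <- function(object, ...) object$fitted.values

#' @export
residuals.biseg_fit <- function(object, ...) object$residuals

#' Plot a hinge fit: starvation response with the fitted two-segment line
#'
#' @param x a `biseg_fit`.
#' @param ... passed to `plot()` for the data points.
#' @export
plot.biseg_fit <- function(x, ...) {
  m <- x$model
  plot(m$age, m$ttp, xlab = "age at starvation (hr AL3E)",
       ylab = "time to pupariation (hr)",
       main = if (!is.null(x$group)) x$group else "starvation response", ...)
  ages <- seq(min(m$age), max(m$age), length.out = 200)
  lines(ages, predict(x, ages), col = "firebrick", lwd = 2)
  abline(v = x$tau, lty = 2, col = "grey40")
  invisible(x)
}

#' Simulate responses from a fitted hinge model
#'
#' Draws new times to pupariation at the fitted ages from the estimated mean
#' function plus Gaussian noise with the fit's residual SD.
#'
#' @param object a `biseg_fit`.
#' @param nsim number of simulated response vectors.
#' @param seed RNG seed (the caller's RNG stream is left untouched).
#' @param ... unused.
#' @return data frame with `nsim` columns, one simulated response per column.
#' @export
simulate.biseg_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  s <- if (is.finite(object$sigma)) object$sigma else 0
  with_seed(seed, {
    as.data.frame(setNames(
      lapply(seq_len(nsim), function(i) mu + rnorm(length(mu), 0, s)),
      paste0("sim_", seq_len(nsim))))
  })
}
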