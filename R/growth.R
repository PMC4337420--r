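# Linear larval growth curve: mass (mg) on age (hr AL3E) during feeding.
# Used to convert a breakpoint age at critical weight into a critical mass.

#' Fit the linear larval growth curve
#'
#' Ordinary least-squares regression of wet mass on age during the feeding
#' period, within one group. Third-instar larvae grow approximately linearly
#' while feeding, which is what licenses converting an age at critical weight
#' into a mass at critical weight.
#'
#' @param records data frame of growth records with numeric columns `age`
#'   (hr AL3E) and `mass` (mg), optionally a `group` column; from
#'   [read_growth_table()] or [simulate_growth()].
#' @param group optional group label; defaults to the records' single group.
#' @return Object of class `"growth_fit"`: list with `intercept` (mg), `slope`
#'   (mg/hr), `residual_sd` (mg), `n`, `group` and the underlying `lm` fit.
#' @examples
#' fit <- fit_growth_curve(data.frame(age = c(0, 10, 20), mass = c(1, 2, 3)))
#' coef(fit)                 # intercept 1, slope 0.1
#' age_to_mass(fit, 8.66)    # 1.866 mg
#' @export
fit_growth_curve <- function(records, group = NULL) {
  records <- as.data.frame(records)
  stopifnot(all(c("age", "mass") %in% names(records)))
  records <- records[complete.cases(records[c("age", "mass")]), , drop = FALSE]
  if (nrow(records) < 3L)
    stop_cw("growth curve needs at least 3 records", "cw_degenerate_design_error")
  if (length(unique(records$age)) < 2L)
    stop_cw("growth curve needs at least 2 distinct ages", "cw_degenerate_design_error")
  if (any(records$mass <= 0))
    stop_cw("larval masses must be positive", "cw_validation_error")
  if (is.null(group) && "group" %in% names(records)) {
    g <- unique(as.character(records$group))
    if (length(g) == 1L) group <- g
  }
  fit <- lm(mass ~ age, data = records)
  structure(list(
    intercept = unname(coef(fit)[1L]),
    slope = unname(coef(fit)[2L]),
    residual_sd = sqrt(sum(residuals(fit)^2) / fit$df.residual),
    n = nrow(records),
    group = group,
    lm = fit
  ), class = "growth_fit")
}

#' Convert an age at critical weight to a mass at critical weight
#'
#' Evaluates the fitted growth line `intercept + slope * age`. By default the
#' conversion refuses to cross group labels: each genotype has its own growth
#' curve, and converting one genotype's breakpoint age through another's
#' growth line is almost never what is wanted.
#'
#' @param fit a `growth_fit`.
#' @param age age(s) in hr AL3E, non-negative.
#' @param group group label of the ages being converted; checked against the
#'   fit's group unless `allow_cross_group = TRUE`. `NULL` skips the check.
#' @param allow_cross_group set `TRUE` to convert across group labels.
#' @return mass in mg (vectorised over `age`). A negative predicted mass is
#'   returned with a warning: it signals extrapolation outside the feeding
#'   period.
#' @export
age_to_mass <- function(fit, age, group = NULL, allow_cross_group = FALSE) {
  stopifnot(inherits(fit, "growth_fit"))
  age <- as.numeric(age)
  if (any(age < 0, na.rm = TRUE))
    stop_cw("ages must be non-negative", "cw_validation_error")
  if (!is.null(group) && !is.null(fit$group) && !allow_cross_group &&
      !identical(as.character(group), as.character(fit$group)))
    stop_cw(sprintf("growth fit is for group '%s', not '%s'; set allow_cross_group = TRUE to override",
                    fit$group, group), "cw_cross_group_error")
  mass <- fit$intercept + fit$slope * age
  if (any(mass < 0, na.rm = TRUE))
    warn_cw("negative predicted mass: age lies outside the feeding period covered by the growth fit",
            "cw_extrapolation_warning")
  mass
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("Linear growth curve", if (!is.null(x$group)) paste0("[", x$group, "]"), "\n")
  cat(sprintf("  mass = %s + %s * age   (mg, hr AL3E)\n",
              format(x$intercept, digits = digits),
              format(x$slope, digits = digits)))
  cat(sprintf("  residual SD = %s mg, n = %d\n",
              format(x$residual_sd, digits = digits), x$n))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  age <- if (is.null(newdata)) object$lm$model$age
         else if (is.data.frame(newdata)) as.numeric(newdata$age)
         else as.numeric(newdata)
  object$intercept + object$slope * age
}

#' @export
residuals.growth_fit <- function(object, ...) residuals(object$lm)

#' @export
summary.growth_fit <- function(object, ...) summary(object$lm)
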