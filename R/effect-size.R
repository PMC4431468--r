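#' Remove confounder influence from an outcome by linear regression
#'
#' Fits ordinary least squares of the outcome on the confounders (with an
#' intercept; factors and logicals are dummy-encoded dropping one level)
#' and appends the residuals as a `.resid` column.  Downstream effect
#' sizes are then computed on the residualised outcome.
#'
#' @param cohort A cohort tibble.
#' @param outcome Name of the outcome column (default `"saf"`).
#' @param confounders Character vector of confounder column names (may be
#'   empty: residuals are then just the centred outcome).
#' @return The input tibble with a `.resid` column, classed
#'   `saf_adjusted`; attributes `coefficients`, `outcome`, `confounders`.
#' @examples
#' cohort <- generate_cohort(calibrate_generator(saf_reference()), seed = 1)
#' adj <- residualize(cohort, "saf", c("age", "diabetes", "bmi", "sr"))
#' tidy(adj)
#' @export
residualize <- function(cohort, outcome = "saf",
                        confounders = c("age", "diabetes", "bmi", "sr")) {
  miss <- setdiff(c(outcome, confounders), names(cohort))
  if (length(miss) > 0) {
    abort(paste0("column(s) not found: ", paste(miss, collapse = ", ")))
  }
  y <- cohort[[outcome]]
  if (!is.numeric(y)) abort("outcome must be numeric")
  if (length(confounders) == 0) {
    x <- matrix(1, nrow(cohort), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    x <- model.matrix(reformulate(confounders), data = cohort)
  }
  if (nrow(x) < nrow(cohort)) abort("missing values in outcome or confounders")
  if (nrow(x) <= ncol(x)) abort("more model terms than subjects")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    dropped <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    abort(paste0("rank-deficient confounder design; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }
  beta <- qr.coef(qx, y)
  out <- cohort
  out$.resid <- as.numeric(y - x %*% beta)
  attr(out, "coefficients") <- setNames(as.numeric(beta), colnames(x))
  attr(out, "outcome") <- outcome
  attr(out, "confounders") <- confounders
  class(out) <- c("saf_adjusted", class(tibble::tibble()))
  out
}

#' @rdname residualize
#' @param x A `saf_adjusted` tibble.
#' @param ... Unused.
#' @export
tidy.saf_adjusted <- function(x, ...) {
  b <- attr(x, "coefficients")
  tibble::tibble(term = names(b), estimate = as.numeric(b))
}

#' Standardized mean difference (Cohen's d) between two groups
#'
#' \eqn{d = (\bar x_1 - \bar x_2)/s} with the pooled standard deviation
#' \eqn{s = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}.  Groups are
#' ordered by first appearance unless `groups` is a factor.  The raw
#' (unstandardised) mean difference is reported alongside `d`, since
#' effect sizes on the SAF scale are conventionally quoted in AU.
#'
#' @param values Numeric outcome vector.
#' @param groups Two-level grouping vector, same length.
#' @param conf.level If non-`NULL`, a noncentral-t confidence interval for
#'   `d` is attached (see [smd_ci()]).
#' @return A one-row tibble of class `saf_effect`: `group1`, `group2`,
#'   `n1`, `n2`, `mean1`, `mean2`, `diff` (AU), `pooled_sd`, `d`, and with
#'   a CI also `ci_low`, `ci_high`, `level`.
#' @examples
#' smd(c(rnorm(30, 2), rnorm(30, 1)), rep(c("a", "b"), each = 30),
#'     conf.level = 0.95)
#' @export
smd <- function(values, groups, conf.level = NULL) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- if (is.factor(groups)) droplevels(groups[keep]) else
    factor(groups[keep], levels = unique(groups[keep]))
  lev <- levels(groups)
  if (length(lev) != 2) abort("exactly two groups are required")
  v1 <- values[groups == lev[1]]
  v2 <- values[groups == lev[2]]
  n1 <- length(v1); n2 <- length(v2)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 observations")
  s <- sqrt(((n1 - 1) * var(v1) + (n2 - 1) * var(v2)) / (n1 + n2 - 2))
  delta <- mean(v1) - mean(v2)
  if (s == 0) {
    if (delta != 0) abort("pooled SD is zero with unequal means: infinite effect")
    d <- 0
  } else {
    d <- delta / s
  }
  out <- tibble::tibble(group1 = lev[1], group2 = lev[2], n1 = n1, n2 = n2,
                        mean1 = mean(v1), mean2 = mean(v2), diff = delta,
                        pooled_sd = s, d = d)
  if (!is.null(conf.level)) {
    ci <- smd_ci(d, n1, n2, level = conf.level)
    out$ci_low <- ci[1]
    out$ci_high <- ci[2]
    out$level <- conf.level
  }
  class(out) <- c("saf_effect", class(out))
  out
}

#' Noncentral-t confidence interval for a standardized mean difference
#'
#' Inverts the noncentral-t distribution of the two-sample statistic
#' \eqn{t = d/\sqrt{1/n_1 + 1/n_2}} with \eqn{n_1+n_2-2} degrees of
#' freedom: the interval endpoints are the noncentrality parameters
#' \eqn{\lambda} at which the observed t sits at the \eqn{(1+level)/2} and
#' \eqn{(1-level)/2} quantiles, scaled back to the d scale.  Roots are
#' found to a tolerance of 1e-8 on \eqn{\lambda}.
#'
#' @param d Observed standardized mean difference.
#' @param n1,n2 Group sizes (each at least 2).
#' @param level Confidence level in (0, 1).
#' @return Length-2 numeric: lower and upper bound for `d`.
#' @export
smd_ci <- function(d, n1, n2, level = 0.95) {
  if (n1 < 2 || n2 < 2) abort("n1 and n2 must be at least 2")
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  scale <- sqrt(1 / n1 + 1 / n2)
  t_obs <- d / scale
  df <- n1 + n2 - 2
  lo <- ncp_root(t_obs, df, (1 + level) / 2)
  hi <- ncp_root(t_obs, df, (1 - level) / 2)
  c(lo, hi) * scale
}

# Solve pt(t_obs, df, ncp = lambda) = target for lambda.  The CDF is
# strictly decreasing in lambda; bracket by doubling, then uniroot.
ncp_root <- function(t_obs, df, target, tol = 1e-8) {
  f <- function(l) suppressWarnings(pt(t_obs, df, ncp = l)) - target
  step <- 1
  lower <- t_obs - step
  while (f(lower) < 0 && step < 1e6) {  # f increases as lambda decreases
    step <- step * 2
    lower <- t_obs - step
  }
  step <- 1
  upper <- t_obs + step
  while (f(upper) > 0 && step < 1e6) {
    step <- step * 2
    upper <- t_obs + step
  }
  if (f(lower) < 0 || f(upper) > 0) {
    abort("noncentral-t CI root-finding failed to bracket the solution")
  }
  r <- stats::uniroot(f, c(lower, upper), tol = tol, maxiter = 2000)
  r$root
}

#' Confounder-adjusted group effect size on SAF
#'
#' The effect of a binary factor on the outcome after removing confounder
#' influence: [residualize()] the outcome on the confounders, then compute
#' the standardized mean difference of the residuals between the factor's
#' two levels with a noncentral-t confidence interval.  This mirrors the
#' standard epidemiological procedure for quoting, e.g., the gender effect
#' on SAF adjusted for age, diabetes, BMI and skin reflectance.
#'
#' @param cohort A cohort tibble.
#' @param factor Name of the binary factor column (must not be among the
#'   confounders).
#' @param confounders Character vector of confounder column names.
#' @param level Confidence level.
#' @param outcome Outcome column (default `"saf"`).
#' @return A one-row `saf_effect` tibble with an `adjusted_for` column.
#' @examples
#' cohort <- generate_cohort(calibrate_generator(saf_reference()), seed = 1)
#' adjusted_group_effect(cohort, "gender", c("age", "diabetes", "bmi", "sr"))
#' @export
adjusted_group_effect <- function(cohort, factor,
                                  confounders = c("age", "diabetes", "bmi", "sr"),
                                  level = 0.95, outcome = "saf") {
  if (factor %in% confounders) {
    abort("the factor of interest cannot also be a confounder")
  }
  if (!factor %in% names(cohort)) abort(paste0("column not found: ", factor))
  used <- c(outcome, factor, confounders)
  cc <- cohort[complete.cases(cohort[used]), used]
  f <- cc[[factor]]
  if (length(unique(f)) < 2) abort(paste0("factor '", factor, "' is constant"))
  adj <- residualize(cc, outcome, confounders)
  out <- smd(adj$.resid, f, conf.level = level)
  out$factor <- factor
  out$adjusted_for <- paste(confounders, collapse = "+")
  out
}

#' @export
print.saf_effect <- function(x, ...) {
  cat(sprintf("standardized mean difference: d = %.3f (raw %.3f AU), n = %d/%d\n",
              x$d, x$diff, x$n1, x$n2))
  if ("ci_low" %in% names(x)) {
    cat(sprintf("  %g%% noncentral-t CI for d: [%.3f, %.3f]\n",
                100 * x$level, x$ci_low, x$ci_high))
  }
  if ("adjusted_for" %in% names(x)) cat("  adjusted for:", x$adjusted_for, "\n")
  invisible(x)
}

#' @rdname smd
#' @param x A `saf_effect`.
#' @param ... Unused.
#' @export
tidy.saf_effect <- function(x, ...) tibble::as_tibble(unclass_tbl(x))
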