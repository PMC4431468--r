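#' Stratified SAF summary statistics from a cohort
#'
#' Computes per-stratum n, sample mean and sample SD (n - 1 denominator) of
#' SAF, stratified by gender or by gender with women split at a skin
#' reflectance threshold.  Age groups are defined by inclusive upper
#' breaks; the default breaks reproduce the reference age grouping
#' (18-19, 20-29, ..., 60-69, 70-99).
#'
#' @param cohort A cohort tibble with `gender`, `age`, `saf` (and `sr` when
#'   `by = "gender_sr"`).
#' @param age_breaks Inclusive upper bounds of the age groups, in years.
#' @param by `"gender"` for gender x age strata, `"gender_sr"` to split
#'   women into low/high skin reflectance at `sr_threshold`.
#' @param sr_threshold SR dichotomisation threshold, percent: low is
#'   `sr <= threshold`, high is `sr > threshold`.
#' @return A `saf_reference_table` tibble; when `by = "gender_sr"` an extra
#'   `stratum` column labels `men` / `women_low_sr` / `women_high_sr`.
#'   Empty strata are emitted with `n = 0` and `NA` mean/SD and flagged in
#'   the `flag` column (`"empty"`, `"sd_undefined"` or `NA`).
#' @export
compute_stratum_stats <- function(cohort, age_breaks = c(19, 29, 39, 49, 59, 69, 99),
                                  by = c("gender", "gender_sr"),
                                  sr_threshold = 10) {
  by <- match.arg(by)
  age_breaks <- sort(age_breaks)
  if (any(cohort$age > max(age_breaks)) || any(cohort$age < 18)) {
    abort("every subject must fall inside the age grouping (18 to max break)")
  }
  lows <- c(18, head(age_breaks, -1) + 1)
  highs <- age_breaks
  grp <- findInterval(cohort$age, lows)
  d <- tibble::tibble(age_low = lows[grp], age_high = highs[grp],
                      gender = cohort$gender, saf = cohort$saf)
  if (by == "gender_sr") {
    d$stratum <- assign_stratum(cohort$gender, cohort$sr, sr_threshold)
    keys <- c("stratum", "gender")
  } else {
    keys <- "gender"
  }
  full <- tidyr::expand_grid(
    dplyr::distinct(d[keys]),
    tibble::tibble(age_low = lows, age_high = highs))
  out <- d |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, "age_low", "age_high")))) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_saf = mean(.data$saf),
                     sd_saf = sd(.data$saf), .groups = "drop")
  out <- dplyr::left_join(full, out, by = c(keys, "age_low", "age_high")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)), .data$age_low)
  out$flag <- dplyr::case_when(out$n == 0 ~ "empty",
                               out$n == 1 ~ "sd_undefined",
                               TRUE ~ NA_character_)
  cols <- c(setdiff(keys, "gender"), "gender", "age_low", "age_high",
            "n", "mean_saf", "sd_saf", "flag")
  out <- out[cols]
  structure(out, label = paste0("stratum stats by ", by),
            class = c("saf_reference_table", class(tibble::tibble())))
}

#' Linear reference curves: SAF mean and SD versus age
#'
#' Fits two straight lines to a stratified reference table — stratum mean
#' SAF versus age-group midpoint, and stratum SD versus midpoint — by
#' (weighted) least squares, solved in closed form by [stats::lm()].  With
#' `weighting = "by_n"` each age group is weighted by its subject count.
#' The pair of lines is the reference curve underlying the risk scheme:
#' boundaries are `mean(age) + k * sd(age)`.
#'
#' @param ref A `saf_reference_table` (pre-filter to one gender/stratum,
#'   or use `gender`).
#' @param label Stratum label stored on the curve (e.g. `"men"`).
#' @param weighting `"by_n"` (default) or `"unweighted"`.
#' @param gender Optional convenience filter applied to `ref`.
#' @param age_domain Age range over which the curve is considered valid;
#'   defaults to the span of the age groups used in the fit.  The fitted SD
#'   line must be strictly positive over this domain.
#' @return An object of class `saf_curve` with [tidy()], [glance()],
#'   [autoplot()] and [evaluate_curve()] support.
#' @examples
#' men <- fit_reference_curve(saf_reference(), label = "men", gender = "M")
#' evaluate_curve(men, age = c(30, 50, 70))
#' @export
fit_reference_curve <- function(ref, label = "all", weighting = c("by_n", "unweighted"),
                                gender = NULL, age_domain = NULL) {
  weighting <- match.arg(weighting)
  if (!is.null(gender)) ref <- ref[ref$gender %in% gender, ]
  ref <- ref[ref$n >= 1 & is.finite(ref$mean_saf) & is.finite(ref$sd_saf), ]
  if (nrow(ref) < 2) abort("underdetermined: need at least 2 usable strata")
  mid <- age_group_midpoint(ref$age_low, ref$age_high)
  if (length(unique(mid)) < 2) {
    abort("singular fit: all age-group midpoints are identical")
  }
  w <- if (weighting == "by_n") ref$n else rep(1, nrow(ref))
  fit_m <- lm(ref$mean_saf ~ mid, weights = w)
  fit_s <- lm(ref$sd_saf ~ mid, weights = w)
  new_saf_curve(
    label = label,
    mean_intercept = unname(coef(fit_m)[1]), mean_slope = unname(coef(fit_m)[2]),
    sd_intercept = unname(coef(fit_s)[1]), sd_slope = unname(coef(fit_s)[2]),
    age_domain = age_domain %||% c(min(ref$age_low), max(ref$age_high)),
    weighting = weighting,
    data = tibble::tibble(midpoint = mid, mean_saf = ref$mean_saf,
                          sd_saf = ref$sd_saf, n = ref$n, weight = w))
}

#' Construct a reference curve from explicit coefficients
#'
#' Used for externally supplied schemes (e.g. a conventional scheme whose
#' coefficients arrive via configuration) and by [fit_reference_curve()].
#' Construction fails if the SD line is not strictly positive everywhere in
#' the age domain.
#'
#' @param label Stratum label.
#' @param mean_intercept,mean_slope Mean-SAF line, AU and AU/year.
#' @param sd_intercept,sd_slope SD line, AU and AU/year.
#' @param age_domain Two-element age range (years).
#' @param weighting,data Fit metadata (optional).
#' @return A `saf_curve`.
#' @export
new_saf_curve <- function(label, mean_intercept, mean_slope, sd_intercept,
                          sd_slope, age_domain = c(18, 99),
                          weighting = "by_n", data = NULL) {
  curve <- structure(
    list(label = label,
         mean_intercept = mean_intercept, mean_slope = mean_slope,
         sd_intercept = sd_intercept, sd_slope = sd_slope,
         age_domain = as.numeric(age_domain), weighting = weighting,
         data = data),
    class = "saf_curve")
  sd_ends <- sd_intercept + sd_slope * curve$age_domain
  if (any(sd_ends <= 0)) {
    abort(paste0("invalid reference curve '", label,
                 "': fitted SD is not positive over the age domain [",
                 curve$age_domain[1], ", ", curve$age_domain[2], "]"))
  }
  curve
}

#' Evaluate a reference curve at given ages
#'
#' @param curve A `saf_curve`.
#' @param age Ages in years.  Ages outside the curve's domain raise an
#'   extrapolation warning but are still evaluated.
#' @return A tibble with `age`, `mean`, `sd` (AU).
#' @export
evaluate_curve <- function(curve, age) {
  stopifnot(inherits(curve, "saf_curve"))
  outside <- age < curve$age_domain[1] | age > curve$age_domain[2]
  if (any(outside)) {
    warn(paste0("extrapolating reference curve '", curve$label, "' outside [",
                curve$age_domain[1], ", ", curve$age_domain[2], "] for ",
                sum(outside), " age value(s)"))
  }
  m <- curve$mean_intercept + curve$mean_slope * age
  s <- curve$sd_intercept + curve$sd_slope * age
  if (any(s <= 0)) {
    abort(paste0("reference curve '", curve$label,
                 "' evaluates to non-positive SD: invalid scheme region"))
  }
  tibble::tibble(age = age, mean = m, sd = s)
}

#' Subject-level SAF-versus-age regression
#'
#' Ordinary least squares of SAF on age at the subject level, the
#' cross-check for the canonical group-midpoint fit (the two agree closely
#' on cohorts with a linear age trend).
#'
#' @param cohort A cohort tibble with `age` and `saf`.
#' @return A tibble with `term`, `estimate`, `std.error`.
#' @export
saf_age_regression <- function(cohort) {
  fit <- lm(saf ~ age, data = cohort)
  sm <- summary(fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2])
}

#' @export
print.saf_curve <- function(x, ...) {
  cat("<saf_curve> ", x$label, "\n",
      sprintf("  mean(age) = %.4f %+.4f * age  [AU]\n", x$mean_intercept, x$mean_slope),
      sprintf("  sd(age)   = %.4f %+.4f * age  [AU]\n", x$sd_intercept, x$sd_slope),
      sprintf("  age domain: %g-%g, weighting: %s\n",
              x$age_domain[1], x$age_domain[2], x$weighting), sep = "")
  invisible(x)
}

#' @rdname fit_reference_curve
#' @param x A `saf_curve`.
#' @param ... Unused.
#' @export
tidy.saf_curve <- function(x, ...) {
  tibble::tibble(
    model = rep(c("mean", "sd"), each = 2),
    term = rep(c("(Intercept)", "age"), 2),
    estimate = c(x$mean_intercept, x$mean_slope, x$sd_intercept, x$sd_slope))
}

#' @rdname fit_reference_curve
#' @export
glance.saf_curve <- function(x, ...) {
  tibble::tibble(label = x$label, mean_slope = x$mean_slope,
                 sd_slope = x$sd_slope, age_min = x$age_domain[1],
                 age_max = x$age_domain[2], weighting = x$weighting,
                 n_groups = if (is.null(x$data)) NA_integer_ else nrow(x$data))
}

#' @rdname fit_reference_curve
#' @param object A `saf_curve`.
#' @export
autoplot.saf_curve <- function(object, ...) {
  ages <- seq(object$age_domain[1], object$age_domain[2], length.out = 50)
  ev <- evaluate_curve(object, ages)
  p <- ggplot(ev, aes(x = .data$age)) +
    geom_line(aes(y = .data$mean)) +
    geom_line(aes(y = .data$mean + .data$sd), linetype = "dashed") +
    geom_line(aes(y = .data$mean + 2 * .data$sd), linetype = "dotted") +
    labs(x = "Age [years]", y = "SAF [AU]", title = object$label)
  if (!is.null(object$data)) {
    p <- p + geom_point(data = object$data,
                        aes(x = .data$midpoint, y = .data$mean_saf,
                            size = .data$n), alpha = 0.6) +
      scale_size_area(max_size = 4, guide = "none")
  }
  p
}
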