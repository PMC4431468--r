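#' Assign subjects to risk-scheme strata
#'
#' The gender- and skin-reflectance-specific scheme uses three strata: all
#' men; women with low skin reflectance (`sr <= threshold`); women with
#' high skin reflectance (`sr > threshold`).  SR is ignored for men.
#'
#' @param gender Character vector of `"M"`/`"F"`.
#' @param sr Skin reflectance, percent (may be `NA` for men).
#' @param sr_threshold Dichotomisation threshold, percent (default 10).
#' @return Character vector of `"men"`, `"women_low_sr"`, `"women_high_sr"`.
#' @examples
#' assign_stratum(c("M", "F", "F"), c(NA, 10, 10.1))
#' @export
assign_stratum <- function(gender, sr, sr_threshold = 10) {
  if (!all(gender %in% c("M", "F"))) abort("gender must be 'M' or 'F'")
  if (any(gender == "F" & is.na(sr))) {
    abort("women with missing SR cannot be assigned a stratum")
  }
  dplyr::case_when(gender == "M" ~ "men",
                   sr <= sr_threshold ~ "women_low_sr",
                   TRUE ~ "women_high_sr")
}

#' Build an SD-multiplier risk stratification scheme
#'
#' A risk scheme attaches, to each stratum, age-dependent boundaries
#' `b_k(age) = mean(age) + m_k * sd(age)` derived from the stratum's
#' reference curve.  With the default multipliers `c(1, 2)` this yields
#' three ordinal risk groups: group 0 (no elevated risk, SAF below
#' mean + 1 SD), group 1 (limited increase, between mean + 1 SD and
#' mean + 2 SD) and group 2+ (increased or definite risk, at or above
#' mean + 2 SD; the two top categories are merged).
#'
#' @param curves Named list of `saf_curve` objects covering `men`,
#'   `women_low_sr` and `women_high_sr`.
#' @param multipliers Strictly increasing positive SD multiples.
#' @param sr_threshold SR threshold used for stratum assignment, percent.
#' @param name Free-text scheme name.
#' @return An object of class `saf_risk_scheme`.
#' @export
build_scheme <- function(curves, multipliers = c(1, 2), sr_threshold = 10,
                         name = "proposed") {
  miss <- setdiff(.saf_strata, names(curves))
  if (length(miss) > 0) {
    abort(paste0("scheme construction error: missing stratum curve(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (length(multipliers) < 2 || any(multipliers <= 0) ||
      any(diff(multipliers) <= 0)) {
    abort("multipliers must be strictly increasing and positive")
  }
  for (s in .saf_strata) {
    if (!inherits(curves[[s]], "saf_curve")) {
      abort(paste0("curve for stratum '", s, "' is not a saf_curve"))
    }
    # boundary ordering over the domain follows from sd > 0 (checked at
    # curve construction) and increasing multipliers; verify anyway
    ev <- evaluate_curve(curves[[s]], curves[[s]]$age_domain)
    b <- outer(ev$sd, multipliers) + ev$mean
    if (any(apply(b, 1, diff) <= 0)) {
      abort(paste0("boundary curves cross within the age domain for '", s, "'"))
    }
  }
  structure(list(name = name, curves = curves[.saf_strata],
                 multipliers = multipliers, sr_threshold = sr_threshold),
            class = "saf_risk_scheme")
}

#' Fit the proposed risk scheme directly from a cohort
#'
#' Convenience wrapper: computes gender/SR-stratified reference statistics,
#' fits one reference curve per stratum and assembles the scheme.
#'
#' @inheritParams compute_stratum_stats
#' @inheritParams build_scheme
#' @param weighting Passed to [fit_reference_curve()].
#' @return A `saf_risk_scheme`.
#' @export
fit_risk_scheme <- function(cohort, age_breaks = c(19, 29, 39, 49, 59, 69, 99),
                            multipliers = c(1, 2), sr_threshold = 10,
                            weighting = "by_n", name = "proposed") {
  stats <- compute_stratum_stats(cohort, age_breaks, by = "gender_sr",
                                 sr_threshold = sr_threshold)
  curves <- purrr::map(setNames(.saf_strata, .saf_strata), function(s) {
    fit_reference_curve(stats[stats$stratum == s, ], label = s,
                        weighting = weighting)
  })
  build_scheme(curves, multipliers, sr_threshold, name)
}

#' Classify subjects into risk groups
#'
#' Each subject is assigned to a stratum ([assign_stratum()]), the stratum
#' boundaries are evaluated at the subject's age, and a group is assigned
#' with the half-open convention: group 0 iff `saf < b1`, group 1 iff
#' `b1 <= saf < b2`, group 2+ iff `saf >= b2` (ties escalate — the
#' conservative choice for a screening tool).  Ages outside a curve's
#' domain raise an extrapolation warning but are still classified.
#'
#' @param cohort A cohort tibble with `gender`, `age`, `sr`, `saf` (and
#'   `id` if present, carried through).
#' @param scheme A `saf_risk_scheme`.
#' @return A tibble with `id`, `stratum`, `b1`, `b2` (AU) and `group`
#'   (ordered factor `0 < 1 < 2+`).
#' @examples
#' cohort <- generate_cohort(calibrate_generator(saf_reference()), seed = 1)
#' scheme <- fit_risk_scheme(cohort)
#' dplyr::count(classify_risk(cohort, scheme), .data$group)
#' @export
classify_risk <- function(cohort, scheme) {
  stopifnot(inherits(scheme, "saf_risk_scheme"))
  if (any(!is.finite(cohort$saf))) abort("non-finite SAF values cannot be classified")
  stratum <- assign_stratum(cohort$gender, cohort$sr, scheme$sr_threshold)
  out <- tibble::tibble(
    id = if ("id" %in% names(cohort)) cohort$id else as.character(seq_len(nrow(cohort))),
    stratum = stratum, age = cohort$age, saf = cohort$saf,
    b1 = NA_real_, b2 = NA_real_)
  m <- scheme$multipliers
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    ev <- evaluate_curve(scheme$curves[[s]], cohort$age[idx])
    out$b1[idx] <- ev$mean + m[1] * ev$sd
    out$b2[idx] <- ev$mean + m[length(m)] * ev$sd
  }
  out$group <- factor(
    dplyr::case_when(out$saf < out$b1 ~ "0",
                     out$saf < out$b2 ~ "1",
                     TRUE ~ "2+"),
    levels = .saf_groups, ordered = TRUE)
  out
}

#' Risk-group distributions under one or more schemes
#'
#' Classifies the cohort under each scheme and tabulates counts and
#' percentages per stratum and risk group (percentages sum to 100 within a
#' scheme x stratum row group; empty groups are kept with explicit zeros).
#' With exactly two schemes a subject-level migration cross-tabulation
#' between the two group assignments is also returned.
#'
#' @param cohort A cohort tibble.
#' @param schemes A named list of `saf_risk_scheme`s (a bare scheme is
#'   wrapped in a list).
#' @return An object of class `saf_scheme_comparison`: list with
#'   `distribution` (tibble: scheme, stratum, group, n, pct) and
#'   `migration` (tibble or `NULL`).
#' @export
compare_schemes <- function(cohort, schemes) {
  if (inherits(schemes, "saf_risk_scheme")) schemes <- list(schemes)
  if (length(schemes) == 0) abort("at least one scheme is required")
  if (is.null(names(schemes)) || any(names(schemes) == "")) {
    names(schemes) <- purrr::map_chr(schemes, function(s) s$name)
  }
  cls <- purrr::map(schemes, function(s) classify_risk(cohort, s))
  distribution <- purrr::imap(cls, function(cl, nm) {
    cl |>
      dplyr::mutate(stratum = factor(.data$stratum, levels = .saf_strata)) |>
      dplyr::count(.data$stratum, .data$group, .drop = FALSE) |>
      dplyr::group_by(.data$stratum) |>
      dplyr::mutate(pct = 100 * .data$n / max(sum(.data$n), 1)) |>
      dplyr::ungroup() |>
      dplyr::mutate(scheme = nm, stratum = as.character(.data$stratum),
                    .before = 1)
  }) |>
    dplyr::bind_rows()
  migration <- NULL
  if (length(cls) == 2) {
    migration <- tibble::tibble(from = cls[[1]]$group, to = cls[[2]]$group) |>
      dplyr::count(.data$from, .data$to, .drop = FALSE) |>
      dplyr::rename(!!paste0(names(cls)[1], "_group") := "from",
                    !!paste0(names(cls)[2], "_group") := "to")
  }
  structure(list(distribution = distribution, migration = migration,
                 schemes = names(schemes)),
            class = "saf_scheme_comparison")
}

#' @export
print.saf_risk_scheme <- function(x, ...) {
  cat("<saf_risk_scheme> ", x$name, "\n  multipliers: ",
      paste(x$multipliers, collapse = ", "), "; SR threshold: ",
      x$sr_threshold, "%\n", sep = "")
  for (s in names(x$curves)) {
    c <- x$curves[[s]]
    cat(sprintf("  %-14s mean = %.3f %+.4f*age, sd = %.3f %+.4f*age\n",
                s, c$mean_intercept, c$mean_slope, c$sd_intercept, c$sd_slope))
  }
  invisible(x)
}

#' @export
print.saf_scheme_comparison <- function(x, ...) {
  cat("<saf_scheme_comparison> schemes:", paste(x$schemes, collapse = " vs "), "\n")
  print(x$distribution, n = 30)
  invisible(x)
}

#' @rdname compare_schemes
#' @param object A `saf_scheme_comparison`.
#' @param ... Unused.
#' @export
autoplot.saf_scheme_comparison <- function(object, ...) {
  ggplot(object$distribution,
         aes(x = .data$group, y = .data$pct, fill = .data$scheme)) +
    geom_col(position = "dodge") +
    facet_wrap(~stratum) +
    labs(x = "Risk group", y = "% of stratum", fill = NULL)
}

#' Risk-band plot for a scheme
#'
#' Shows, per stratum, the age-dependent risk bands (group 0 below
#' mean + 1 SD, group 1 up to mean + 2 SD, group 2+ above) with optional
#' subject points overlaid.
#'
#' @param object A `saf_risk_scheme`.
#' @param cohort Optional cohort tibble to overlay.
#' @param ... Unused.
#' @export
autoplot.saf_risk_scheme <- function(object, cohort = NULL, ...) {
  bands <- purrr::imap(object$curves, function(curve, s) {
    ages <- seq(curve$age_domain[1], curve$age_domain[2], length.out = 60)
    ev <- evaluate_curve(curve, ages)
    m <- object$multipliers
    tibble::tibble(stratum = s, age = ev$age,
                   b1 = ev$mean + m[1] * ev$sd,
                   b2 = ev$mean + m[length(m)] * ev$sd)
  }) |> dplyr::bind_rows()
  ymax <- max(bands$b2) * 1.2
  p <- ggplot(bands, aes(x = .data$age)) +
    geom_ribbon(aes(ymin = 0, ymax = .data$b1, fill = "0"), alpha = 0.35) +
    geom_ribbon(aes(ymin = .data$b1, ymax = .data$b2, fill = "1"), alpha = 0.35) +
    geom_ribbon(aes(ymin = .data$b2, ymax = ymax, fill = "2+"), alpha = 0.35) +
    geom_line(aes(y = .data$b1)) + geom_line(aes(y = .data$b2)) +
    facet_wrap(~stratum) +
    scale_fill_manual(values = c("0" = "#4daf4a", "1" = "#ffb000", "2+" = "#e41a1c")) +
    labs(x = "Age [years]", y = "SAF [AU]", fill = "Risk group",
         title = object$name)
  if (!is.null(cohort)) {
    pts <- tibble::tibble(
      stratum = assign_stratum(cohort$gender, cohort$sr, object$sr_threshold),
      age = cohort$age, saf = cohort$saf)
    p <- p + geom_point(data = pts, aes(y = .data$saf), size = 0.3, alpha = 0.3)
  }
  p
}

#' Read or write a risk scheme as a structured YAML document
#'
#' @param scheme A `saf_risk_scheme`.
#' @param path File path.
#' @return `read_scheme()` returns a `saf_risk_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  doc <- list(
    name = scheme$name,
    multipliers = as.numeric(scheme$multipliers),
    sr_threshold = scheme$sr_threshold,
    strata = purrr::map(scheme$curves, function(c) {
      list(mean_intercept = c$mean_intercept, mean_slope = c$mean_slope,
           sd_intercept = c$sd_intercept, sd_slope = c$sd_slope,
           age_min = c$age_domain[1], age_max = c$age_domain[2])
    }))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  doc <- yaml::read_yaml(path)
  curves <- purrr::imap(doc$strata, function(s, nm) {
    new_saf_curve(nm, s$mean_intercept, s$mean_slope, s$sd_intercept,
                  s$sd_slope, c(s$age_min, s$age_max))
  })
  build_scheme(curves, multipliers = as.numeric(doc$multipliers),
               sr_threshold = doc$sr_threshold, name = doc$name)
}
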