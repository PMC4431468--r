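#' Default marginal summaries for cohort calibration
#'
#' The marginal targets the generator is calibrated against when no other
#' margins are supplied: the skin-reflectance mean/SD and measurability
#' floor, per-gender categorical counts (diabetes, smoking, exercise,
#' nationality, hypertension), anthropometric marginal means/SDs, and the
#' target correlation structure among height, weight, waist, hip and blood
#' pressure.  Defaults describe the Saudi study cohort (1122 men, 877
#' women): SR mean 9.5% (SD 3.0, floor 6%), 163/121 diabetic men/women,
#' 328/64 smokers, exercise category counts per gender, and strongly
#' correlated weight/waist/hip (pairwise r >= 0.82 in the copula, so that
#' weight, BMI, waist and hip end up with sample r > 0.81).
#'
#' Hypertension prevalence is not part of the published categorical table;
#' the default assumes 25% per gender, a realistic adult prevalence for the
#' region, and only feeds the hypertension flag (an O-PLSR predictor and
#' effect-size factor), not the SAF calibration.
#'
#' @return A list with components `sr`, `gender_totals`, `prevalence`,
#'   `anthropometrics` and `covariate_effects`; see Details in
#'   [calibrate_generator()].
#' @export
saf_cohort_margins <- function() {
  corr <- matrix(c(
    1.00, 0.35, 0.15, 0.15, 0.10, 0.05,
    0.35, 1.00, 0.86, 0.86, 0.30, 0.25,
    0.15, 0.86, 1.00, 0.86, 0.28, 0.24,
    0.15, 0.86, 0.86, 1.00, 0.20, 0.18,
    0.10, 0.30, 0.28, 0.20, 1.00, 0.65,
    0.05, 0.25, 0.24, 0.18, 0.65, 1.00), 6, 6, byrow = TRUE)
  vars <- c("height", "weight", "waist", "hip", "sbp", "dbp")
  dimnames(corr) <- list(vars, vars)
  list(
    sr = list(mean = 9.5, sd = 3.0, min = 6),
    gender_totals = c(M = 1122, F = 877),
    prevalence = list(
      M = list(diabetes = 163, smoking = 328, hypertension = 280, saudi = 640,
               exercise = c("none" = 530, "1-2/month" = 142,
                            "1-2/week" = 207, "3+/week" = 243)),
      F = list(diabetes = 121, smoking = 64, hypertension = 219, saudi = 503,
               exercise = c("none" = 464, "1-2/month" = 88,
                            "1-2/week" = 156, "3+/week" = 169))
    ),
    anthropometrics = list(
      variables = vars,
      corr = corr,
      marginals = list(
        M = list(mean = c(height = 1.70, weight = 86.4, waist = 101,
                          hip = 107, sbp = 131, dbp = 79),
                 sd = c(height = 0.07, weight = 17, waist = 14,
                        hip = 11, sbp = 15, dbp = 11)),
        F = list(mean = c(height = 1.56, weight = 72.5, waist = 94,
                          hip = 109, sbp = 121, dbp = 75),
                 sd = c(height = 0.07, weight = 15, waist = 13,
                        hip = 13, sbp = 16, dbp = 11))
      ),
      bounds = list(height = c(1.22, 2.10), weight = c(35, 170),
                    waist = c(50, 170), hip = c(55, 190),
                    sbp = c(80, 230), dbp = c(40, 190))
    ),
    covariate_effects = list(diabetes_shift_M = 0.41, diabetes_shift_F = 0.53,
                             bmi_coeff_M = 0.02, sr_coeff_F = 0.064)
  )
}

#' Calibrate the synthetic cohort generator from a reference table
#'
#' Builds a generator configuration whose stratum parameters mirror the
#' reference table exactly (same gender x age-group cells, same n, same SAF
#' mean/SD) and whose marginal targets (skin reflectance, categorical
#' prevalences, anthropometric structure, injected covariate effects) come
#' from `margins`.  A cohort generated from the resulting configuration
#' reproduces the reference SAF mean/SD per stratum in expectation and the
#' categorical counts exactly.
#'
#' @param reference A [saf_reference()]-style `saf_reference_table`.
#' @param margins Marginal summaries as produced by [saf_cohort_margins()].
#' @param saf_distribution Shape of the within-stratum SAF noise:
#'   `"normal"` (default; truncated at 0.5 AU) or `"lognormal"` (right-
#'   skewed, matching the skew of the real cohort).
#' @param adjust_female_total If `TRUE`, two extra women are added to the
#'   female 30-39 stratum so the female total matches the published cohort
#'   size of 877 (the stratified table itself sums to 875).  Default
#'   `FALSE`: stratum n are taken verbatim from the reference.
#' @param seed Optional default seed stored in the configuration.
#' @return A list of class `saf_generator_config`.
#' @examples
#' cfg <- calibrate_generator(saf_reference())
#' sum(cfg$strata$n)  # 1997
#' @export
calibrate_generator <- function(reference, margins = saf_cohort_margins(),
                                saf_distribution = c("normal", "lognormal"),
                                adjust_female_total = FALSE, seed = NULL) {
  if (is.null(reference) || nrow(reference) == 0) {
    abort("calibration error: reference table is empty")
  }
  validate_reference_table(reference)
  if (any(!is.finite(reference$sd_saf)) || any(reference$sd_saf <= 0)) {
    abort("validation error: every reference stratum must have sd_saf > 0")
  }
  saf_distribution <- match.arg(saf_distribution)
  strata <- tibble::tibble(
    gender = reference$gender,
    age_low = reference$age_low,
    age_high = reference$age_high,
    n = as.integer(reference$n),
    saf_mean = reference$mean_saf,
    saf_sd = reference$sd_saf
  )
  if (adjust_female_total) {
    i <- which(strata$gender == "F" & strata$age_low <= 35 & strata$age_high >= 35)
    if (length(i) == 1) strata$n[i] <- strata$n[i] + 2L
  }
  if (margins$sr$sd <= 0) abort("validation error: SR sd must be positive")
  structure(
    list(strata = strata,
         sr = margins$sr,
         gender_totals = margins$gender_totals,
         prevalence = margins$prevalence,
         anthropometrics = margins$anthropometrics,
         covariate_effects = margins$covariate_effects,
         saf_distribution = saf_distribution,
         seed = seed),
    class = "saf_generator_config")
}

# Rescale a vector of category counts (stated for `from_total` subjects) to
# sum exactly to `to_total`, by largest-remainder rounding.  Deterministic.
rescale_counts <- function(counts, from_total, to_total) {
  if (from_total == to_total) return(counts)
  quota <- counts / from_total * to_total
  out <- floor(quota)
  short <- to_total - sum(out)
  if (short > 0) {
    take <- order(quota - out, decreasing = TRUE)[seq_len(short)]
    out[take] <- out[take] + 1
  }
  as.integer(out)
}

# Permutation assignment of a binary flag with an exact count of TRUEs.
assign_exact <- function(n, n_true) {
  n_true <- min(max(n_true, 0L), n)
  sample(c(rep(TRUE, n_true), rep(FALSE, n - n_true)))
}

.exercise_levels <- c("none", "1-2/month", "1-2/week", "3+/week")

#' Generate a synthetic SAF cohort
#'
#' Draws a full subject-level cohort from a generator configuration.  The
#' generator is exact where the calibration targets are counts and
#' stochastic where they are moments:
#' \itemize{
#'   \item per-stratum subject counts equal the configured `n` exactly;
#'   \item categorical flags (diabetes, smoking, hypertension, nationality,
#'     exercise) are assigned by permutation with exact per-gender counts,
#'     rescaled deterministically if the generated gender total differs from
#'     the margins' stated total;
#'   \item ages are uniform integers within each age group (the open-ended
#'     top group draws on 70-80);
#'   \item height, weight, waist, hip and blood pressures come from a
#'     Gaussian copula with the configured correlation matrix; BMI and
#'     waist:hip ratio are recomputed from their components;
#'   \item SR is `sr_min` plus a Gamma variate with moments chosen so the
#'     marginal mean/SD equal the configured values despite the 6% floor;
#'   \item SAF is the stratum mean plus centred covariate effects (diabetes
#'     shift per gender, BMI effect in men, SR effect in women) plus noise
#'     whose variance is chosen so the stratum marginal SD matches the
#'     configuration in expectation; values are truncated at 0.5 AU.
#' }
#' The same configuration and seed always reproduce the identical cohort.
#'
#' @param config A `saf_generator_config` from [calibrate_generator()].
#' @param seed Integer seed; mandatory (falls back to `config$seed`).
#' @return A tibble with one row per subject and columns `id`, `gender`,
#'   `age`, `nationality`, `height`, `weight`, `bmi`, `waist`, `hip`,
#'   `whr`, `sbp`, `dbp`, `sr`, `saf`, `diabetes`, `hypertension`,
#'   `smoking`, `exercise`; attributes `seed` and `provenance`.
#' @examples
#' cohort <- generate_cohort(calibrate_generator(saf_reference()), seed = 1)
#' nrow(cohort)
#' @export
generate_cohort <- function(config, seed = config$seed) {
  if (!inherits(config, "saf_generator_config")) {
    abort("config must be created by calibrate_generator()")
  }
  if (is.null(seed)) abort("a seed is mandatory for cohort generation")
  seed <- as.integer(seed)
  withr::with_seed(seed, generate_cohort_impl(config, seed))
}

generate_cohort_impl <- function(config, seed) {
  strata <- config$strata
  n_total <- sum(strata$n)
  if (n_total == 0) abort("configuration has no subjects to generate")

  # demographic skeleton: exact stratum counts, uniform integer ages
  per_stratum <- purrr::pmap(strata, function(gender, age_low, age_high, n,
                                              saf_mean, saf_sd) {
    hi <- min(age_high, 80)  # no support beyond 80 in the top group
    ages <- seq(age_low, hi)
    tibble::tibble(gender = gender,
                   age = if (n > 0) ages[sample.int(length(ages), n, replace = TRUE)]
                         else integer(0),
                   stratum = paste(gender, age_low, age_high, sep = "_"))
  })
  cohort <- dplyr::bind_rows(per_stratum)
  cohort$id <- sprintf("S%05d", seq_len(nrow(cohort)))

  # exact-count categorical assignment, per gender, in M/F order
  cohort$diabetes <- NA
  cohort$smoking <- NA
  cohort$hypertension <- NA
  cohort$nationality <- NA_character_
  cohort$exercise <- NA_character_
  for (g in c("M", "F")) {
    idx <- which(cohort$gender == g)
    n_g <- length(idx)
    if (n_g == 0) next
    prev <- config$prevalence[[g]]
    stated <- unname(config$gender_totals[g])
    scale1 <- function(k) rescale_counts(c(k, stated - k), stated, n_g)[1]
    cohort$diabetes[idx] <- assign_exact(n_g, scale1(prev$diabetes))
    cohort$smoking[idx] <- assign_exact(n_g, scale1(prev$smoking))
    cohort$hypertension[idx] <- assign_exact(n_g, scale1(prev$hypertension))
    cohort$nationality[idx] <-
      sample(rep(c("Saudi Arabian", "Other"),
                 c(scale1(prev$saudi), n_g - scale1(prev$saudi))))
    ex <- rescale_counts(prev$exercise, sum(prev$exercise), n_g)
    cohort$exercise[idx] <- sample(rep(names(prev$exercise), ex))
  }
  cohort$exercise <- factor(cohort$exercise, levels = .exercise_levels,
                            ordered = TRUE)

  # anthropometrics via Gaussian copula per gender
  anth <- config$anthropometrics
  ch <- chol(anth$corr)
  vars <- anth$variables
  for (v in vars) cohort[[v]] <- NA_real_
  for (g in c("M", "F")) {
    idx <- which(cohort$gender == g)
    if (length(idx) == 0) next
    z <- matrix(rnorm(length(idx) * length(vars)), ncol = length(vars)) %*% ch
    marg <- anth$marginals[[g]]
    for (j in seq_along(vars)) {
      v <- vars[j]
      x <- marg$mean[[v]] + marg$sd[[v]] * z[, j]
      b <- anth$bounds[[v]]
      cohort[[v]][idx] <- pmin(pmax(x, b[1]), b[2])
    }
  }
  cohort$bmi <- cohort$weight / cohort$height^2
  cohort$whr <- cohort$waist / cohort$hip

  # SR: floor + Gamma, moment-matched so mean/SD hold despite the floor
  m <- config$sr$mean - config$sr$min
  if (config$sr$sd > 0 && m > 0) {
    shape <- (m / config$sr$sd)^2
    rate <- m / config$sr$sd^2
    cohort$sr <- config$sr$min + rgamma(nrow(cohort), shape = shape, rate = rate)
  } else {
    cohort$sr <- rep(config$sr$mean, nrow(cohort))
  }

  # SAF: stratum mean + centred covariate effects + variance-matched noise
  eff <- config$covariate_effects
  lin <- ifelse(cohort$gender == "M",
                eff$diabetes_shift_M * cohort$diabetes +
                  eff$bmi_coeff_M * cohort$bmi,
                eff$diabetes_shift_F * cohort$diabetes +
                  eff$sr_coeff_F * cohort$sr)
  cohort$saf <- NA_real_
  for (s in unique(cohort$stratum)) {
    idx <- which(cohort$stratum == s)
    n_s <- length(idx)
    row <- strata[match(s, paste(strata$gender, strata$age_low,
                                 strata$age_high, sep = "_")), ]
    l <- lin[idx] - mean(lin[idx])
    var_l <- if (n_s > 1) var(l) else 0
    sig <- sqrt(max(row$saf_sd^2 - var_l, (0.1 * row$saf_sd)^2))
    eps <- draw_noise(n_s, sig, config$saf_distribution)
    saf <- row$saf_mean + l + eps
    for (k in 1:50) {  # resample the rare sub-floor draws
      bad <- which(saf < 0.5)
      if (length(bad) == 0) break
      saf[bad] <- row$saf_mean + l[bad] +
        draw_noise(length(bad), sig, config$saf_distribution)
    }
    cohort$saf[idx] <- pmax(saf, 0.5)
  }

  out <- cohort[, c("id", "gender", "age", "nationality", "height", "weight",
                    "bmi", "waist", "hip", "whr", "sbp", "dbp", "sr", "saf",
                    "diabetes", "hypertension", "smoking", "exercise")]
  out <- tibble::as_tibble(out)
  attr(out, "seed") <- seed
  attr(out, "provenance") <-
    paste0("safref::generate_cohort(seed = ", seed, "); ", nrow(out),
           " subjects; distribution = ", config$saf_distribution)
  out
}

# Mean-zero noise with the given SD; lognormal variant keeps the right skew
# of real SAF data (fixed shape, sdlog = 0.5).
draw_noise <- function(n, sig, family) {
  if (family == "lognormal") {
    mu <- exp(0.125)
    s <- sqrt((exp(0.25) - 1) * exp(0.25))
    (stats::rlnorm(n, 0, 0.5) - mu) / s * sig
  } else {
    rnorm(n, 0, sig)
  }
}
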