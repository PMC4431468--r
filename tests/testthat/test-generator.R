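test_that("calibration mirrors the reference table and rejects bad input", {
  ref <- saf_reference()
  cfg <- calibrate_generator(ref)
  expect_equal(nrow(cfg$strata), 14)
  expect_equal(sum(cfg$strata$n), 1997)
  expect_equal(cfg$strata$saf_mean, ref$mean_saf)
  expect_equal(cfg$strata$saf_sd, ref$sd_saf)

  one <- as_reference_table(tibble::tibble(
    gender = "M", age_low = 20, age_high = 29, n = 10,
    mean_saf = 2.0, sd_saf = 0.4))
  cfg1 <- calibrate_generator(one)
  expect_equal(cfg1$strata$n, 10L)
  expect_equal(cfg1$strata$saf_mean, 2.0)
  expect_equal(cfg1$strata$saf_sd, 0.4)

  expect_error(calibrate_generator(ref[0, ]), "empty")
  zero_sd <- ref
  zero_sd$sd_saf[5] <- 0
  expect_error(calibrate_generator(zero_sd), "sd_saf > 0")

  adj <- calibrate_generator(ref, adjust_female_total = TRUE)
  expect_equal(sum(adj$strata$n), 1999)
  expect_equal(adj$strata$n[adj$strata$gender == "F" &
                              adj$strata$age_low == 30], 286L)
})

test_that("generation is deterministic and seeded", {
  cfg <- calibrate_generator(saf_reference())
  expect_error(generate_cohort(cfg), "seed")
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a$saf, c$saf))
  # serialization is byte-identical across regenerations
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(a, p1)
  write_cohort(b, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("categorical margins are assigned exactly, not sampled", {
  cohort <- test_cohort()
  counts <- dplyr::count(cohort, gender, diabetes)
  expect_equal(counts$n[counts$gender == "M" & counts$diabetes], 163L)
  expect_equal(counts$n[counts$gender == "F" & counts$diabetes], 121L)
  expect_equal(sum(cohort$smoking[cohort$gender == "M"]), 328L)
  expect_equal(sum(cohort$smoking[cohort$gender == "F"]), 64L)
  ex_m <- table(cohort$exercise[cohort$gender == "M"])
  expect_equal(as.integer(ex_m), c(530L, 142L, 207L, 243L))
  # exact for any seed (assignment by permutation)
  other <- generate_cohort(calibrate_generator(saf_reference()), seed = 777)
  expect_equal(sum(other$diabetes[other$gender == "M"]), 163L)
})

test_that("stratum sizes are exact and ages stay inside their groups", {
  cohort <- test_cohort()
  ref <- saf_reference()
  tab <- compute_stratum_stats(cohort)
  merged <- dplyr::inner_join(
    tibble::as_tibble(as.data.frame(ref)),
    tibble::as_tibble(as.data.frame(tab)),
    by = c("gender", "age_low", "age_high"), suffix = c("_ref", "_obs"))
  expect_equal(nrow(merged), 14)
  expect_equal(merged$n_obs, merged$n_ref)
  expect_true(all(cohort$age >= 18 & cohort$age <= 80))
})

test_that("stratified SAF moments recover the calibration across all strata", {
  cohort <- test_cohort()
  ref <- saf_reference()
  tab <- compute_stratum_stats(cohort)
  merged <- dplyr::inner_join(
    tibble::as_tibble(as.data.frame(ref)),
    tibble::as_tibble(as.data.frame(tab)),
    by = c("gender", "age_low", "age_high"), suffix = c("_ref", "_obs"))
  # mean within 3*SD/sqrt(n), SD within 3*SD/sqrt(2n), per stratum
  tol_mean <- 3 * merged$sd_saf_ref / sqrt(merged$n_ref)
  tol_sd <- 3 * merged$sd_saf_ref / sqrt(2 * merged$n_ref)
  expect_true(all(abs(merged$mean_saf_obs - merged$mean_saf_ref) < tol_mean))
  expect_true(all(abs(merged$sd_saf_obs - merged$sd_saf_ref) < tol_sd))
})

test_that("skin reflectance marginal matches its calibration", {
  cohort <- test_cohort()
  n <- nrow(cohort)
  expect_true(all(cohort$sr >= 6))
  expect_lt(abs(mean(cohort$sr) - 9.5), 3 * 3.0 / sqrt(n))
  expect_lt(abs(sd(cohort$sr) - 3.0), 0.3)
  expect_gt(mean(cohort$sr < 11), 0.5)  # majority below 11%
})

test_that("anthropometrics are internally consistent and strongly correlated", {
  cohort <- test_cohort()
  expect_true(all(abs(cohort$bmi - cohort$weight / cohort$height^2) <
                    0.005 * cohort$bmi))
  expect_true(all(abs(cohort$whr - cohort$waist / cohort$hip) <
                    0.005 * cohort$whr))
  for (g in c("M", "F")) {
    sub <- cohort[cohort$gender == g, ]
    cm <- cor(sub[c("weight", "bmi", "waist", "hip")])
    expect_true(all(cm[upper.tri(cm)] > 0.81))
  }
})

test_that("injected covariate effects are recoverable within a stratum", {
  cfg <- calibrate_generator(saf_reference())
  cohort <- test_cohort()
  men <- cohort[cohort$gender == "M" & cohort$age >= 30 & cohort$age <= 39, ]
  fit <- summary(lm(saf ~ bmi + diabetes, data = men))$coefficients
  expect_lt(abs(fit["bmi", 1] - cfg$covariate_effects$bmi_coeff_M),
            3 * fit["bmi", 2])
  expect_lt(abs(fit["diabetesTRUE", 1] - cfg$covariate_effects$diabetes_shift_M),
            3 * fit["diabetesTRUE", 2])
  women <- cohort[cohort$gender == "F" & cohort$age >= 30 & cohort$age <= 39, ]
  fitw <- summary(lm(saf ~ sr + diabetes, data = women))$coefficients
  expect_lt(abs(fitw["sr", 1] - cfg$covariate_effects$sr_coeff_F),
            3 * fitw["sr", 2])
})

test_that("stratum means converge over repeated seeds", {
  # for a large stratum, |sample mean - config mean| < 3 SD/sqrt(n) in at
  # least 95% of seeds (here: all of a small seed panel)
  cfg <- calibrate_generator(saf_reference())
  hits <- vapply(1:10, function(s) {
    cohort <- generate_cohort(cfg, seed = s)
    m <- cohort[cohort$gender == "M" & cohort$age >= 30 & cohort$age <= 39, ]
    abs(mean(m$saf) - 1.75) < 3 * 0.42 / sqrt(nrow(m))
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("lognormal SAF option keeps the calibrated moments but adds skew", {
  ref <- saf_reference()
  cfg <- calibrate_generator(ref, saf_distribution = "lognormal")
  cohort <- generate_cohort(cfg, seed = 31)
  m <- cohort[cohort$gender == "M" & cohort$age >= 30 & cohort$age <= 39, ]
  expect_lt(abs(mean(m$saf) - 1.75), 3 * 0.42 / sqrt(nrow(m)))
  skew <- mean((m$saf - mean(m$saf))^3) / sd(m$saf)^3
  expect_gt(skew, 0.3)
})
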