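test_that("residualization reduces to centring and zeroes exact fits", {
  d <- tibble::tibble(saf = c(1, 2, 3, 4, 5, 6), age = 1:6,
                      bmi = c(2, 1, 4, 3, 6, 5))
  adj0 <- residualize(d, "saf", character(0))
  expect_equal(adj0$.resid, d$saf - mean(d$saf))

  d$saf <- 0.5 + 0.1 * d$age + 0.2 * d$bmi
  adj <- residualize(d, "saf", c("age", "bmi"))
  expect_true(all(abs(adj$.resid) <= 1e-9))
  expect_lt(abs(sum(adj$.resid)), 1e-9)

  d$age2 <- d$age * 2
  expect_error(residualize(d, "saf", c("age", "age2")), "age2")
})

test_that("residualization recovers injected confounder slopes", {
  cohort <- test_cohort()
  women <- cohort[cohort$gender == "F", ]
  adj <- residualize(women, "saf", c("age", "sr", "diabetes"))
  b <- attr(adj, "coefficients")
  fit <- summary(lm(saf ~ age + sr + diabetes, data = women))$coefficients
  expect_equal(unname(b["sr"]), fit["sr", 1], tolerance = 1e-10)
  # the generator's female SR coefficient is recovered within 3 SE
  cfg <- calibrate_generator(saf_reference())
  expect_lt(abs(b[["sr"]] - cfg$covariate_effects$sr_coeff_F),
            3 * fit["sr", 2])
})

test_that("standardized mean difference follows the pooled-SD formula", {
  v <- withr::with_seed(2, rnorm(10, 2, 1))
  same <- smd(c(v, v), rep(c("a", "b"), each = 10))
  expect_equal(same$d, 0)

  withr::with_seed(3, {
    v1 <- rnorm(10); v1 <- (v1 - mean(v1)) / sd(v1) + 2  # mean 2, sd 1
    v2 <- rnorm(10); v2 <- (v2 - mean(v2)) / sd(v2) + 1  # mean 1, sd 1
  })
  r <- smd(c(v1, v2), rep(c("hi", "lo"), each = 10))
  expect_equal(r$d, 1.0, tolerance = 1e-12)
  expect_equal(r$diff, 1.0, tolerance = 1e-12)

  # antisymmetry under label swap, CI bounds swap and negate
  g <- rep(c("x", "y"), each = 10)
  a <- smd(c(v1, v2), factor(g, c("x", "y")), conf.level = 0.95)
  b <- smd(c(v1, v2), factor(g, c("y", "x")), conf.level = 0.95)
  expect_equal(b$d, -a$d)
  expect_equal(b$ci_low, -a$ci_high, tolerance = 1e-7)
  expect_equal(b$ci_high, -a$ci_low, tolerance = 1e-7)

  expect_error(smd(c(1, 1, 2, 2), rep("a", 4)), "two groups")
  expect_error(smd(c(1, 1, 2, 2), c("a", "a", "b", "b")), "infinite effect")
})

test_that("smd is invariant under affine transformation of the values", {
  withr::with_seed(8, {
    v <- rnorm(40, 2, 0.5)
    g <- sample(rep(c("a", "b"), 20))
  })
  d0 <- smd(v, g)$d
  expect_equal(smd(3 * v + 7, g)$d, d0, tolerance = 1e-12)
  expect_equal(smd(-2 * v, g)$d, -d0, tolerance = 1e-12)
})

test_that("noncentral-t interval matches the bisection oracle", {
  cases <- expand.grid(d = c(0, 0.3, 0.8, -0.5), n1 = c(30, 120),
                       n2 = c(30, 55))
  for (i in seq_len(nrow(cases))) {
    d <- cases$d[i]; n1 <- cases$n1[i]; n2 <- cases$n2[i]
    ci <- smd_ci(d, n1, n2, level = 0.95)
    sc <- sqrt(1 / n1 + 1 / n2)
    t_obs <- d / sc
    lo <- ncp_bisect_oracle(t_obs, n1 + n2 - 2, 0.975) * sc
    hi <- ncp_bisect_oracle(t_obs, n1 + n2 - 2, 0.025) * sc
    expect_equal(ci[1], lo, tolerance = 1e-6)
    expect_equal(ci[2], hi, tolerance = 1e-6)
  }
  # symmetry about zero at d = 0 with equal n
  ci0 <- smd_ci(0, 25, 25)
  expect_equal(ci0[1], -ci0[2], tolerance = 1e-7)
})

test_that("interval width shrinks with sample size", {
  widths <- vapply(c(10, 25, 60, 150, 400), function(n) {
    diff(smd_ci(0.8, n, n, level = 0.95))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("the interval covers the true effect at its nominal level", {
  # moderate Monte Carlo here; the full-size calibration run lives in the
  # acceptance suite
  n_sim <- 2000
  d_true <- 0.5
  covered <- withr::with_seed(17, {
    vapply(seq_len(n_sim), function(i) {
      x1 <- rnorm(20, d_true, 1)
      x2 <- rnorm(20, 0, 1)
      r <- smd(c(x1, x2), rep(c("a", "b"), each = 20), conf.level = 0.95)
      r$ci_low <= d_true && d_true <= r$ci_high
    }, logical(1))
  })
  expect_lt(abs(mean(covered) - 0.95), 0.015)
})

test_that("adjustment leaves orthogonal factors untouched and absorbs mediated ones", {
  withr::with_seed(23, {
    n <- 3000
    g <- sample(rep(c("a", "b"), n / 2))
    age <- runif(n, 20, 70)            # independent of g
    saf <- 1 + 0.01 * age + 0.3 * (g == "a") + rnorm(n, 0, 0.4)
    d1 <- tibble::tibble(saf = saf, grp = g, age = age)
  })
  raw <- smd(d1$saf, d1$grp)
  adj <- adjusted_group_effect(d1, "grp", "age")
  se <- sqrt(1 / raw$n1 + 1 / raw$n2 + raw$d^2 / (2 * (raw$n1 + raw$n2)))
  expect_lt(abs(adj$d - raw$d), 3 * se)

  # effect flowing only through a confounder vanishes after adjustment
  withr::with_seed(29, {
    n <- 3000
    g2 <- sample(rep(c("a", "b"), n / 2))
    bmi <- 28 + 3 * (g2 == "a") + rnorm(n, 0, 4)
    saf2 <- 1 + 0.05 * bmi + rnorm(n, 0, 0.4)   # g only acts via bmi
    d2 <- tibble::tibble(saf = saf2, grp = g2, bmi = bmi)
  })
  adj2 <- adjusted_group_effect(d2, "grp", "bmi")
  se2 <- sqrt(1 / adj2$n1 + 1 / adj2$n2)
  expect_lt(abs(adj2$d), 3 * se2)

  expect_error(adjusted_group_effect(d2, "bmi", "bmi"), "confounder")
  d2$const <- "z"
  expect_error(adjusted_group_effect(d2, "const", "bmi"), "constant")
})

test_that("adjusted effect estimation is unbiased at cohort scale", {
  # 200 replicates of n = 2000 with a known standardized gender effect
  d_true <- 0.5
  ests <- withr::with_seed(37, {
    vapply(seq_len(200), function(i) {
      n <- 2000
      gender <- rep(c("M", "F"), n / 2)
      age <- runif(n, 18, 80)
      bmi <- rnorm(n, 30, 6)
      sr <- 6 + rgamma(n, 1.36, 0.39)
      noise_sd <- 0.4
      saf <- 1 + 0.012 * age + 0.01 * bmi + 0.02 * sr +
        d_true * noise_sd * (gender == "F") + rnorm(n, 0, noise_sd)
      d <- tibble::tibble(saf = saf, gender = gender, age = age,
                          bmi = bmi, sr = sr)
      adjusted_group_effect(d, "gender", c("age", "bmi", "sr"),
                            level = NULL)$d
    }, numeric(1))
  })
  # gender levels: first appearance is M, so d = (M - F)/s = -d_true
  expect_lt(abs(mean(ests) - (-d_true)), 0.05)
})
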