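# Shared fixtures and independent oracles.  Everything here is built in
# code at test time; the oracles deliberately avoid the package's own code
# paths.

# Default-calibrated cohort at a fixed seed, built once per test run.
.fixtures <- new.env(parent = emptyenv())
test_cohort <- function(seed = 424242) {
  key <- paste0("cohort", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_cohort(calibrate_generator(saf_reference()),
                                        seed = seed)
  }
  .fixtures[[key]]
}

# Hand-coded weighted least squares via the normal equations (2x2 solve),
# independent of stats::lm.
wls_oracle <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
  sy <- sum(w * y); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  c(intercept = (sxx * sy - sx * sxy) / det,
    slope = (sw * sxy - sx * sy) / det)
}

# Bisection inversion of the noncentral-t CDF over lambda, on a coarse
# bracket refined to `tol`.  Independent of the package's root finder.
ncp_bisect_oracle <- function(t_obs, df, target, tol = 1e-9) {
  f <- function(l) suppressWarnings(stats::pt(t_obs, df, ncp = l)) - target
  lo <- t_obs - 50
  hi <- t_obs + 50
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Single-component PLS1 computed directly (center, unit-variance scale,
# one covariance-weight projection), independent of fit_oplsr().
pls1_oracle_predict <- function(x, y, x_new = x) {
  x <- as.matrix(x)
  ctr <- colMeans(x); scl <- apply(x, 2, sd)
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  yc <- mean(y); ysd <- sd(y)
  ys <- (y - yc) / ysd
  w <- crossprod(xs, ys)[, 1]
  w <- w / sqrt(sum(w^2))
  t1 <- xs %*% w
  c1 <- sum(ys * t1) / sum(t1^2)
  ns <- sweep(sweep(as.matrix(x_new), 2, ctr), 2, scl, "/")
  as.numeric((ns %*% w) * c1 * ysd + yc)
}

# Simulated regression data with known linear signal.
make_signal_data <- function(n = 500, p = 8, snr = 10, seed = 1) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    beta <- seq(1, 2, length.out = p)
    signal <- as.numeric(x %*% beta)
    noise_sd <- sd(signal) / sqrt(snr)
    list(x = x, y = signal + rnorm(n, 0, noise_sd))
  })
}

# Cohort-like table with a known linear SAF-age trend and pure noise
# around it (no covariate structure).
make_linear_cohort <- function(n = 4000, intercept = 1.2, slope = 0.016,
                               sd = 0.4, seed = 99) {
  withr::with_seed(seed, {
    age <- sample(18:79, n, replace = TRUE)
    tibble::tibble(
      id = as.character(seq_len(n)),
      gender = sample(c("M", "F"), n, replace = TRUE),
      age = age,
      sr = 6 + rgamma(n, shape = 1.361, rate = 0.389),
      saf = intercept + slope * age + rnorm(n, 0, sd))
  })
}
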