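test_that("with no orthogonal components the model is exactly PLS1", {
  sim <- make_signal_data(n = 80, p = 6, snr = 5, seed = 61)
  fit <- fit_oplsr(sim$x, sim$y, n_ortho = 0)
  oracle <- pls1_oracle_predict(sim$x, sim$y)
  expect_lt(max(abs(predict(fit, sim$x) - oracle)), 1e-8)
})

test_that("the PLS1 reduction agrees with an established implementation", {
  skip_if_not_installed("mixOmics")
  sim <- make_signal_data(n = 60, p = 5, snr = 5, seed = 67)
  fit <- fit_oplsr(sim$x, sim$y, n_ortho = 0)
  m <- mixOmics::pls(sim$x, sim$y, ncomp = 1, mode = "regression",
                     scale = TRUE)
  pred <- predict(m, sim$x)$predict[, 1, 1]
  expect_lt(max(abs(predict(fit, sim$x) - pred)), 1e-6)
})

test_that("predictive scores are orthogonal to every orthogonal score", {
  sim <- make_signal_data(n = 150, p = 8, snr = 3, seed = 71)
  for (k in 1:3) {
    fit <- fit_oplsr(sim$x, sim$y, n_ortho = k)
    for (j in seq_len(k)) {
      expect_lt(abs(sum(fit$t_pred * fit$t_ortho[[j]])), 1e-8)
    }
  }
})

test_that("y-orthogonal structure is isolated by the orthogonal components", {
  sim <- make_signal_data(n = 300, p = 6, snr = 10, seed = 73)
  # an extra column orthogonal to the outcome and to every predictor
  # cannot touch the predictive path: training predictions are unchanged
  withr::with_seed(74, z0 <- rnorm(300))
  z <- as.numeric(scale(resid(lm(z0 ~ sim$x + sim$y))))
  x_aug <- cbind(sim$x, noise = 3 * z)
  clean <- fit_oplsr(sim$x, sim$y, n_ortho = 1)
  aug <- fit_oplsr(x_aug, sim$y, n_ortho = 1)
  expect_lt(max(abs(predict(aug, x_aug) - predict(clean, sim$x))), 1e-6)

  # rank-one y-orthogonal contamination spread across the predictors is
  # located by the orthogonal component and predictive power recovers
  withr::with_seed(75, {
    z2 <- as.numeric(scale(resid(lm(rnorm(300) ~ sim$y))))
    v <- rnorm(6)
  })
  x_con <- sim$x + 2 * z2 %*% t(v)
  con1 <- fit_oplsr(x_con, sim$y, n_ortho = 1)
  expect_gt(abs(cor(con1$t_ortho[[1]], z2)), 0.9)
  q_pls <- oplsr_cv(x_con, sim$y, n_ortho = 0, seed = 5)$q2y
  q_opls <- oplsr_cv(x_con, sim$y, n_ortho = 1, seed = 5)$q2y
  expect_gt(q_opls, q_pls)
})

test_that("strong linear signal is captured", {
  sim <- make_signal_data(n = 500, p = 8, snr = 10, seed = 79)
  fit <- fit_oplsr(sim$x, sim$y, n_ortho = 1)
  expect_gt(fit$r2y, 0.85)
  expect_true(fit$r2x >= 0 && fit$r2x <= 1)
  expect_true(fit$r2y >= 0 && fit$r2y <= 1)
})

test_that("fit validates its inputs", {
  sim <- make_signal_data(n = 40, p = 4, seed = 83)
  xz <- sim$x
  xz[, 2] <- 5
  expect_error(fit_oplsr(xz, sim$y), "zero-variance.*x2")
  expect_error(fit_oplsr(sim$x, sim$y, n_ortho = 4), "rank")
  expect_error(fit_oplsr(sim$x[1:5, ], sim$y[1:5]), "at least 10")
  expect_error(fit_oplsr(sim$x[, 1, drop = FALSE], sim$y), "2 predictor")
})

test_that("prediction identities hold", {
  sim <- make_signal_data(n = 200, p = 6, snr = 5, seed = 89)
  fit <- fit_oplsr(sim$x, sim$y, n_ortho = 1)
  # training predictions reproduce the stored fit exactly
  expect_lt(max(abs(predict(fit, sim$x) - fit$fitted)), 1e-10)
  # the training mean row predicts the training y mean
  mrow <- matrix(colMeans(sim$x), 1, dimnames = list(NULL, colnames(sim$x)))
  expect_equal(predict(fit, mrow), mean(sim$y), tolerance = 1e-10)
  # adding the orthogonal loading direction to rows leaves predictions
  # unchanged
  shift <- fit$p_ortho[[1]] * fit$x_scale
  x_shift <- sweep(sim$x, 2, -2 * shift)
  expect_lt(max(abs(predict(fit, x_shift) - predict(fit, sim$x))), 1e-8)
  expect_error(predict(fit, sim$x[, 1:3]), "columns")
})

test_that("explained X variance grows with orthogonal components", {
  sim <- make_signal_data(n = 150, p = 8, snr = 2, seed = 97)
  r2x <- vapply(0:3, function(k) fit_oplsr(sim$x, sim$y, k)$r2x, numeric(1))
  expect_true(all(diff(r2x) >= -1e-10))
})

test_that("cross-validation is honest: Q2Y below R2Y, noise near zero, signal close", {
  # optimism inequality across many simulated datasets
  res <- purrr::map_dfr(1:100, function(i) {
    sim <- make_signal_data(n = 100, p = 6, snr = 2, seed = 1000 + i)
    fit <- fit_oplsr(sim$x, sim$y, n_ortho = 1)
    cv <- oplsr_cv(sim$x, sim$y, n_ortho = 1, seed = i)
    tibble::tibble(r2y = fit$r2y, q2y = cv$q2y)
  })
  expect_true(all(res$q2y <= res$r2y))

  # pure-noise outcome: Q2Y at or below ~0 in nearly all runs
  noise_q2 <- vapply(1:20, function(i) {
    withr::with_seed(2000 + i, {
      x <- matrix(rnorm(100 * 6), 100, 6)
      y <- rnorm(100)
    })
    oplsr_cv(x, y, n_ortho = 1, seed = i)$q2y
  }, numeric(1))
  expect_gte(sum(noise_q2 <= 0.05), 19)

  # strong signal: Q2Y within 0.1 of R2Y
  sim <- make_signal_data(n = 400, p = 8, snr = 10, seed = 101)
  fit <- fit_oplsr(sim$x, sim$y, n_ortho = 1)
  cv <- oplsr_cv(sim$x, sim$y, n_ortho = 1, seed = 7)
  expect_lt(abs(fit$r2y - cv$q2y), 0.1)
})

test_that("fold assignment is seeded, stratified and guarded", {
  sim <- make_signal_data(n = 50, p = 4, seed = 103)
  a <- oplsr_cv(sim$x, sim$y, seed = 9)
  b <- oplsr_cv(sim$x, sim$y, seed = 9)
  expect_identical(a$q2y, b$q2y)
  expect_error(oplsr_cv(sim$x[1:10, ], sim$y[1:10], folds = 7), "fewer than 2")
})

test_that("permutation validation separates signal from chance", {
  sim <- make_signal_data(n = 300, p = 8, snr = 10, seed = 107)
  perm <- oplsr_permutation(sim$x, sim$y, n_ortho = 1, n_perm = 999, seed = 11)
  expect_lte(perm$p_q2y, 0.01)
  expect_gt(perm$observed_q2y, max(perm$null_q2y))
  # add-one formula holds exactly
  expect_equal(perm$p_q2y,
               (1 + sum(perm$null_q2y >= perm$observed_q2y)) / 1000)
  expect_error(oplsr_permutation(sim$x, sim$y, n_perm = 50), "99")
})

test_that("permutation p-values are uniform under the null", {
  ps <- vapply(1:100, function(i) {
    withr::with_seed(3000 + i, {
      x <- matrix(rnorm(60 * 5), 60, 5)
      y <- rnorm(60)
    })
    oplsr_permutation(x, y, n_ortho = 1, n_perm = 99, seed = i)$p_q2y
  }, numeric(1))
  expect_lt(abs(mean(ps <= 0.1) - 0.10), 0.06)
})

test_that("models survive a full-precision text round trip", {
  sim <- make_signal_data(n = 60, p = 5, seed = 109)
  fit <- fit_oplsr(sim$x, sim$y, n_ortho = 1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_oplsr(fit, path)
  back <- read_oplsr(path)
  expect_equal(predict(back, sim$x), predict(fit, sim$x), tolerance = 1e-12)
})
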