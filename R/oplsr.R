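#' Orthogonal partial least squares regression (O-PLSR)
#'
#' Fits a single-response O-PLS model: predictor variation is split into
#' one predictive latent component (covarying with the outcome) and
#' `n_ortho` components orthogonal to the outcome, which are removed
#' before the predictive projection.  With `n_ortho = 0` the model reduces
#' exactly to single-component PLS1.
#'
#' Predictors and outcome are mean-centred; predictors are scaled to unit
#' variance by default (`"uv"`), or by the square root of the SD
#' (`"pareto"`).  Logical and factor predictors are expanded to 0/1
#' dummies (dropping one level) before scaling.
#'
#' The orthogonal components are extracted iteratively: on the current
#' predictor matrix the PLS weight `w` is computed, the X-loading `p` of
#' its score is projected off `w` to give the orthogonal weight, and the
#' resulting orthogonal score/loading pair is deflated from X.  The
#' predictive component is then fitted on the fully deflated matrix.
#'
#' Reported diagnostics: `r2x`, the fraction of (scaled) predictor
#' variance captured by all components; `r2y`, the fraction of outcome
#' variance explained in fit.  Cross-validated prediction accuracy (Q2Y)
#' comes from [oplsr_cv()].
#'
#' @param x Predictor data frame or numeric matrix (at least 2 columns,
#'   10 rows, no missing values).
#' @param y Numeric outcome vector.
#' @param n_ortho Number of orthogonal components (0 or more; must be
#'   below the predictor rank).
#' @param scaling `"uv"` (unit variance, default) or `"pareto"`.
#' @return An object of class `saf_oplsr` with [predict()], [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @examples
#' cohort <- generate_cohort(calibrate_generator(saf_reference()), seed = 1)
#' men <- dplyr::filter(cohort, gender == "M")
#' fit <- fit_oplsr(men[c("age", "bmi", "whr", "sbp", "dbp", "sr",
#'                        "diabetes", "hypertension", "smoking")],
#'                  men$saf, n_ortho = 1)
#' glance(fit)
#' @export
fit_oplsr <- function(x, y, n_ortho = 1, scaling = c("uv", "pareto")) {
  scaling <- match.arg(scaling)
  xm <- as_predictor_matrix(x)
  y <- as.numeric(y)
  if (nrow(xm) != length(y)) abort("nrow(x) must equal length(y)")
  if (anyNA(xm) || anyNA(y)) abort("missing values are not allowed")
  if (length(y) < 10) abort("at least 10 observations are required")
  if (ncol(xm) < 2) abort("at least 2 predictor columns are required")
  x_center <- colMeans(xm)
  x_sd <- apply(xm, 2, sd)
  zero <- colnames(xm)[x_sd == 0]
  if (length(zero) > 0) {
    abort(paste0("zero-variance predictor column(s): ",
                 paste(zero, collapse = ", ")))
  }
  x_scale <- if (scaling == "uv") x_sd else sqrt(x_sd)
  xs <- sweep(sweep(xm, 2, x_center), 2, x_scale, "/")
  rank_x <- qr(xs)$rank
  if (n_ortho >= rank_x) {
    abort(paste0("n_ortho (", n_ortho, ") must be below the predictor rank (",
                 rank_x, ")"))
  }
  y_center <- mean(y)
  y_scale <- sd(y)
  if (y_scale == 0) abort("outcome has zero variance")
  ys <- (y - y_center) / y_scale

  ssx_total <- sum(xs^2)
  xd <- xs
  w_o <- p_o <- t_o <- list()
  for (j in seq_len(n_ortho)) {
    comp <- extract_ortho(xd, ys)
    if (is.null(comp)) {
      abort("no orthogonal variation left to extract; reduce n_ortho")
    }
    w_o[[j]] <- comp$w_o
    t_o[[j]] <- comp$t_o
    p_o[[j]] <- comp$p_o
    xd <- xd - tcrossprod(comp$t_o, comp$p_o)
  }
  w <- crossprod(xd, ys)[, 1]
  w <- w / sqrt(sum(w^2))
  t_p <- as.numeric(xd %*% w)
  p_p <- crossprod(xd, t_p)[, 1] / sum(t_p^2)
  c_y <- sum(ys * t_p) / sum(t_p^2)

  fitted_s <- t_p * c_y
  r2y <- 1 - sum((ys - fitted_s)^2) / sum(ys^2)
  ssx_comp <- sum(vapply(seq_along(t_o), function(j) {
    sum(t_o[[j]]^2) * sum(p_o[[j]]^2)
  }, numeric(1))) + sum(t_p^2) * sum(p_p^2)
  r2x <- ssx_comp / ssx_total

  structure(
    list(variables = colnames(xm), n_ortho = n_ortho, scaling = scaling,
         x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale,
         w_pred = w, p_pred = p_p, t_pred = t_p, y_loading = c_y,
         w_ortho = w_o, p_ortho = p_o, t_ortho = t_o,
         r2x = r2x, r2y = r2y, n = length(y),
         fitted = fitted_s * y_scale + y_center),
    class = "saf_oplsr")
}

# One y-orthogonal component from the current (scaled, deflated) matrix.
extract_ortho <- function(xd, ys) {
  w <- crossprod(xd, ys)[, 1]
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) return(NULL)
  w <- w / nw
  t_p <- as.numeric(xd %*% w)
  p <- crossprod(xd, t_p)[, 1] / sum(t_p^2)
  w_o <- p - sum(w * p) * w
  nwo <- sqrt(sum(w_o^2))
  if (nwo < 1e-10) return(NULL)
  w_o <- w_o / nwo
  t_o <- as.numeric(xd %*% w_o)
  p_o <- crossprod(xd, t_o)[, 1] / sum(t_o^2)
  list(w_o = w_o, t_o = t_o, p_o = p_o)
}

# Dummy-encode a predictor table: logicals to 0/1, factors/characters to
# treatment dummies dropping the first level.
as_predictor_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    return(x)
  }
  x <- as.data.frame(x)
  for (v in names(x)) {
    if (is.logical(x[[v]])) x[[v]] <- as.numeric(x[[v]])
    if (is.character(x[[v]])) x[[v]] <- factor(x[[v]])
  }
  mm <- model.matrix(~., data = x)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}

#' Predict from a fitted O-PLSR model
#'
#' Applies the stored centring/scaling, removes the fitted orthogonal
#' variation from the new predictor rows, projects onto the predictive
#' component and back-transforms to the outcome scale.
#'
#' @param object A `saf_oplsr`.
#' @param newdata Predictor data with the same columns as at fit time.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.saf_oplsr <- function(object, newdata, ...) {
  xm <- as_predictor_matrix(newdata)
  if (!identical(colnames(xm), object$variables)) {
    if (all(object$variables %in% colnames(xm))) {
      xm <- xm[, object$variables, drop = FALSE]
    } else {
      abort(paste0("predictor columns do not match the training data; expected: ",
                   paste(object$variables, collapse = ", ")))
    }
  }
  xs <- sweep(sweep(xm, 2, object$x_center), 2, object$x_scale, "/")
  for (j in seq_along(object$w_ortho)) {
    t_o <- as.numeric(xs %*% object$w_ortho[[j]])
    xs <- xs - outer(t_o, object$p_ortho[[j]])
  }
  t_p <- as.numeric(xs %*% object$w_pred)
  as.numeric(t_p * object$y_loading * object$y_scale + object$y_center)
}

#' Seven-fold cross-validated Q2Y for an O-PLSR model
#'
#' Q2Y = 1 - PRESS/TSS with out-of-fold predictions: fold assignment is
#' seeded and stratified on outcome quantiles; centring and scaling are
#' recomputed inside each training fold so no information leaks into the
#' held-out fold.  TSS is the total sum of squares about the overall
#' outcome mean.
#'
#' @inheritParams fit_oplsr
#' @param folds Number of folds (default 7).
#' @param seed Integer seed for the fold assignment.
#' @return A list with `q2y` and the per-fold PRESS contributions.
#' @export
oplsr_cv <- function(x, y, n_ortho = 1, folds = 7, seed = 1,
                     scaling = c("uv", "pareto")) {
  scaling <- match.arg(scaling)
  xm <- as_predictor_matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  if (n < folds) abort("need at least as many observations as folds")
  fold <- withr::with_seed(seed, stratified_folds(y, folds))
  if (min(table(fold)) < 2) abort("a fold has fewer than 2 samples")
  press <- numeric(folds)
  for (k in seq_len(folds)) {
    test <- fold == k
    fit <- fit_oplsr(xm[!test, , drop = FALSE], y[!test], n_ortho = n_ortho,
                     scaling = scaling)
    pred <- predict(fit, xm[test, , drop = FALSE])
    press[k] <- sum((y[test] - pred)^2)
  }
  tss <- sum((y - mean(y))^2)
  list(q2y = 1 - sum(press) / tss, press = press, folds = folds, seed = seed)
}

# Quantile-stratified fold assignment: subjects are ranked on y and folds
# dealt cyclically within consecutive rank blocks, with a shuffled deal per
# block.
stratified_folds <- function(y, folds) {
  ord <- order(y, sample.int(length(y)))  # random tie-break
  fold <- integer(length(y))
  blocks <- split(ord, ceiling(seq_along(ord) / folds))
  for (b in blocks) {
    fold[b] <- sample(rep_len(seq_len(folds), length(b)), length(b))
  }
  fold
}

#' Permutation validation of an O-PLSR model
#'
#' Refits the model and its cross-validated Q2Y on `n_perm` outcome
#' shuffles, giving null distributions for R2Y and Q2Y and an add-one
#' permutation p-value for Q2Y:
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @inheritParams oplsr_cv
#' @param n_perm Number of permutations (at least 99).
#' @return An object of class `saf_oplsr_permutation`: observed and null
#'   `r2y`/`q2y` and `p_q2y`.
#' @export
oplsr_permutation <- function(x, y, n_ortho = 1, n_perm = 999, folds = 7,
                              seed = 1, scaling = c("uv", "pareto")) {
  scaling <- match.arg(scaling)
  if (n_perm < 99) abort("n_perm must be at least 99")
  xm <- as_predictor_matrix(x)
  y <- as.numeric(y)
  obs_fit <- fit_oplsr(xm, y, n_ortho = n_ortho, scaling = scaling)
  obs_cv <- oplsr_cv(xm, y, n_ortho = n_ortho, folds = folds, seed = seed,
                     scaling = scaling)
  null_r2y <- null_q2y <- numeric(n_perm)
  perms <- withr::with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample.int(length(y)))
  })
  for (i in seq_len(n_perm)) {
    yp <- y[perms[[i]]]
    null_r2y[i] <- fit_oplsr(xm, yp, n_ortho = n_ortho, scaling = scaling)$r2y
    null_q2y[i] <- oplsr_cv(xm, yp, n_ortho = n_ortho, folds = folds,
                            seed = seed + i, scaling = scaling)$q2y
  }
  structure(
    list(observed_r2y = obs_fit$r2y, observed_q2y = obs_cv$q2y,
         null_r2y = null_r2y, null_q2y = null_q2y, n_perm = n_perm,
         p_q2y = (1 + sum(null_q2y >= obs_cv$q2y)) / (n_perm + 1)),
    class = "saf_oplsr_permutation")
}

#' @export
print.saf_oplsr <- function(x, ...) {
  cat(sprintf("<saf_oplsr> 1 predictive + %d orthogonal component(s), %d x %d\n",
              x$n_ortho, x$n, length(x$variables)))
  cat(sprintf("  R2X = %.3f, R2Y = %.3f (%s scaling)\n", x$r2x, x$r2y, x$scaling))
  invisible(x)
}

#' @export
print.saf_oplsr_permutation <- function(x, ...) {
  cat(sprintf("<saf_oplsr_permutation> %d permutations\n", x$n_perm))
  cat(sprintf("  observed Q2Y = %.3f (null max %.3f), p = %.4g\n",
              x$observed_q2y, max(x$null_q2y), x$p_q2y))
  invisible(x)
}

#' @rdname fit_oplsr
#' @param x,object A fitted `saf_oplsr`.
#' @param ... Unused.
#' @export
tidy.saf_oplsr <- function(x, ...) {
  out <- tibble::tibble(variable = x$variables, component = "predictive",
                        weight = x$w_pred, loading = x$p_pred)
  for (j in seq_along(x$w_ortho)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      variable = x$variables, component = paste0("ortho", j),
      weight = x$w_ortho[[j]], loading = x$p_ortho[[j]]))
  }
  out
}

#' @rdname fit_oplsr
#' @export
glance.saf_oplsr <- function(x, ...) {
  tibble::tibble(n = x$n, p = length(x$variables), n_ortho = x$n_ortho,
                 r2x = x$r2x, r2y = x$r2y, scaling = x$scaling)
}

#' @rdname fit_oplsr
#' @export
autoplot.saf_oplsr <- function(object, ...) {
  sc <- tibble::tibble(
    t_pred = object$t_pred,
    t_ortho = if (object$n_ortho > 0) object$t_ortho[[1]] else
      stats::residuals(lm(object$fitted ~ object$t_pred)))
  ggplot(sc, aes(x = .data$t_pred, y = .data$t_ortho)) +
    geom_point(alpha = 0.5) +
    labs(x = "Predictive score t[1]",
         y = if (object$n_ortho > 0) "Orthogonal score t[o1]" else "residual",
         title = "O-PLSR scores")
}

#' Loading plot for an O-PLSR model
#'
#' @param object A `saf_oplsr`.
#' @param ... Unused.
#' @export
plot_oplsr_loadings <- function(object, ...) {
  ld <- tidy(object)
  ld <- ld[ld$component == "predictive", ]
  ggplot(ld, aes(x = stats::reorder(.data$variable, .data$loading),
                 y = .data$loading)) +
    geom_col() + coord_flip() +
    labs(x = NULL, y = "Predictive loading", title = "O-PLSR loadings")
}

#' @rdname oplsr_permutation
#' @param object A `saf_oplsr_permutation`.
#' @param ... Unused.
#' @export
autoplot.saf_oplsr_permutation <- function(object, ...) {
  ggplot(tibble::tibble(q2y = object$null_q2y), aes(x = .data$q2y)) +
    geom_histogram(bins = 40, fill = "grey60") +
    geom_vline(xintercept = object$observed_q2y, colour = "red") +
    labs(x = "null Q2Y", y = "count",
         title = sprintf("Permutation null (p = %.4g)", object$p_q2y))
}

#' Serialize an O-PLSR model to a structured text document
#'
#' All weights, loadings, scores and scaling vectors are written at full
#' precision to YAML, so a model can be stored and re-used for prediction.
#'
#' @param model A `saf_oplsr`.
#' @param path Output path.
#' @export
write_oplsr <- function(model, path) {
  doc <- purrr::map(unclass(model), function(el) {
    if (is.list(el)) purrr::map(el, as.numeric) else el
  })
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_oplsr
#' @export
read_oplsr <- function(path) {
  doc <- yaml::read_yaml(path)
  num <- c("x_center", "x_scale", "w_pred", "p_pred", "t_pred", "fitted")
  for (v in num) doc[[v]] <- as.numeric(doc[[v]])
  names(doc$x_center) <- names(doc$x_scale) <- doc$variables
  for (v in c("w_ortho", "p_ortho", "t_ortho")) {
    doc[[v]] <- purrr::map(doc[[v]], as.numeric)
  }
  structure(doc, class = "saf_oplsr")
}
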