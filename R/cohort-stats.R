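#' Stratified Pearson correlation matrix with two triangles
#'
#' Computes pairwise-complete Pearson correlations among the given numeric
#' variables separately for two strata (e.g. women vs men, or diabetic vs
#' non-diabetic subjects) and packs them into one square matrix: the upper
#' triangle carries the first stratum, the lower triangle the second.
#' Zero-variance variables yield `NA` cells, flagged with a warning rather
#' than silently reported as 0.
#'
#' @param cohort A cohort tibble.
#' @param variables Names of numeric columns to correlate.
#' @param split_by A two-level column used to split the cohort (default
#'   `"gender"`; a logical column such as `diabetes` also works).
#' @param upper Which level goes into the upper triangle; defaults to the
#'   second sorted level (for gender, `"F"` upper / `"M"` lower,
#'   mirroring the convention of correlation heatmaps for this cohort).
#' @return An object of class `saf_corr` with [tidy()] and [autoplot()]
#'   methods.
#' @export
correlation_matrix <- function(cohort,
                               variables = c("age", "height", "weight", "bmi",
                                             "waist", "hip", "whr", "sbp",
                                             "dbp", "sr", "saf"),
                               split_by = "gender", upper = NULL) {
  variables <- intersect(variables, names(cohort))
  bad <- variables[!purrr::map_lgl(cohort[variables], is.numeric)]
  if (length(bad) > 0) {
    abort(paste0("non-numeric variable(s): ", paste(bad, collapse = ", ")))
  }
  g <- cohort[[split_by]]
  lev <- sort(unique(as.character(g)))
  if (length(lev) != 2) abort(paste0("'", split_by, "' must have exactly two levels"))
  # conventions of the cohort heatmaps: women upper / men lower, and
  # diabetic (TRUE) upper / non-diabetic lower
  upper <- upper %||% (if (identical(lev, c("F", "M"))) "F" else lev[2])
  lower <- setdiff(lev, upper)
  n_up <- sum(g == upper)
  n_lo <- sum(g == lower)
  if (n_up < 3 || n_lo < 3) abort("each stratum needs at least 3 subjects")
  cm_up <- suppressWarnings(
    cor(cohort[g == upper, variables], use = "pairwise.complete.obs"))
  cm_lo <- suppressWarnings(
    cor(cohort[g == lower, variables], use = "pairwise.complete.obs"))
  vals <- cm_lo
  vals[upper.tri(vals)] <- cm_up[upper.tri(cm_up)]
  diag(vals) <- 1
  und <- variables[purrr::map_lgl(variables, function(v) {
    sd_up <- sd(cohort[[v]][g == upper], na.rm = TRUE)
    sd_lo <- sd(cohort[[v]][g == lower], na.rm = TRUE)
    isTRUE(sd_up == 0) || isTRUE(sd_lo == 0)
  })]
  if (length(und) > 0) {
    warn(paste0("zero-variance variable(s), correlations undefined: ",
                paste(und, collapse = ", ")))
  }
  structure(list(values = vals, variables = variables,
                 upper_stratum = upper, lower_stratum = lower,
                 n_upper = n_up, n_lower = n_lo, undefined = und),
            class = "saf_corr")
}

#' @rdname correlation_matrix
#' @param x A `saf_corr`.
#' @param ... Unused.
#' @export
tidy.saf_corr <- function(x, ...) {
  v <- x$variables
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  up <- tibble::tibble(var1 = v[idx[, "row"]], var2 = v[idx[, "col"]],
                       stratum = x$upper_stratum, r = x$values[idx])
  tidx <- which(lower.tri(x$values), arr.ind = TRUE)
  lo <- tibble::tibble(var1 = v[tidx[, "row"]], var2 = v[tidx[, "col"]],
                       stratum = x$lower_stratum, r = x$values[tidx])
  dplyr::bind_rows(up, lo)
}

#' @rdname correlation_matrix
#' @param object A `saf_corr`.
#' @export
autoplot.saf_corr <- function(object, ...) {
  long <- tidy(object)
  long$var1 <- factor(long$var1, levels = object$variables)
  long$var2 <- factor(long$var2, levels = rev(object$variables))
  ggplot(long, aes(x = .data$var1, y = .data$var2, fill = .data$r)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", high = "#b2182b", limits = c(-1, 1)) +
    labs(x = NULL, y = NULL,
         title = paste0("upper: ", object$upper_stratum,
                        ", lower: ", object$lower_stratum)) +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' @export
print.saf_corr <- function(x, ...) {
  cat("<saf_corr> upper triangle:", x$upper_stratum, paste0("(n=", x$n_upper, ")"),
      "| lower:", x$lower_stratum, paste0("(n=", x$n_lower, ")"), "\n")
  print(round(x$values, 2))
  invisible(x)
}

#' Two-group univariate test with normality-gated selection
#'
#' For a numeric outcome: Shapiro-Wilk normality is tested in each group
#' at alpha = 0.05; if both groups pass, a two-sided t test is used,
#' otherwise a two-sided Wilcoxon rank-sum test.  (Shapiro-Wilk is
#' undefined above n = 5000, so larger groups are gated on a fixed-seed
#' subsample of 5000.)  For a 2x2 count table (given as a matrix), a
#' chi-square test with Yates continuity correction is used.
#'
#' @param x Numeric outcome vector, or a 2x2 count matrix/table.
#' @param groups Two-level grouping vector (ignored for a count table).
#' @param shapiro_alpha Normality gate level.
#' @return A one-row tibble: `test` (`"t"`, `"wilcoxon"` or
#'   `"chi-square"`), `statistic`, `p_value`, `normality_used`.
#' @examples
#' univariate_group_test(matrix(c(163, 959, 121, 756), 2, byrow = TRUE))
#' @export
univariate_group_test <- function(x, groups = NULL, shapiro_alpha = 0.05) {
  if (is.matrix(x) || is.table(x)) {
    if (!all(dim(x) == 2)) abort("count table must be 2x2")
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
      abort("expected cell count of zero: chi-square test undefined")
    }
    ht <- chisq.test(x, correct = TRUE)
    return(tibble::tibble(test = "chi-square",
                          statistic = unname(ht$statistic),
                          p_value = ht$p.value, normality_used = NA))
  }
  keep <- !is.na(x) & !is.na(groups)
  x <- x[keep]
  g <- factor(as.character(groups[keep]))
  if (nlevels(g) != 2) abort("exactly two groups are required")
  normal <- all(tapply(x, g, function(v) shapiro_gate(v) >= shapiro_alpha))
  if (normal) {
    ht <- stats::t.test(x ~ g)
    tibble::tibble(test = "t", statistic = unname(ht$statistic),
                   p_value = ht$p.value, normality_used = TRUE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x ~ g))
    tibble::tibble(test = "wilcoxon", statistic = unname(ht$statistic),
                   p_value = ht$p.value, normality_used = FALSE)
  }
}

# Shapiro-Wilk p-value, on a fixed-seed subsample of 5000 when n exceeds
# the test's upper limit.  Constant vectors count as non-normal.
shapiro_gate <- function(v) {
  if (length(v) < 3 || sd(v) == 0) return(0)
  if (length(v) > 5000) {
    v <- withr::with_seed(871, v[sample.int(length(v), 5000)])
  }
  stats::shapiro.test(v)$p.value
}

#' @importFrom stats chisq.test
NULL

#' Descriptive cohort summary in reference-table style
#'
#' Per-group summaries of numeric and categorical variables with the
#' normality-dependent formatting rule: normally distributed variables
#' (Shapiro-Wilk in both groups at alpha = 0.05) are shown as
#' `mean (+/-SD)`, non-normal ones as `median (min-max)`.  Categorical
#' variables are shown as counts.  The p-value column uses
#' [univariate_group_test()] (chi-square for categorical variables).
#'
#' @param cohort A cohort tibble.
#' @param by Two-level grouping column, default `"gender"`.
#' @param variables Columns to summarise; defaults to everything except
#'   `id` and `by`.
#' @return A tibble with `variable`, one formatted column per group,
#'   `test` and `p_value`.
#' @export
summarize_cohort <- function(cohort, by = "gender", variables = NULL) {
  if (nrow(cohort) == 0) abort("cohort is empty")
  variables <- variables %||% setdiff(names(cohort), c("id", by))
  g <- factor(as.character(cohort[[by]]))
  lev <- levels(g)
  if (length(lev) != 2) abort(paste0("'", by, "' must have exactly two levels"))
  rows <- purrr::map(variables, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      normal <- all(tapply(x, g, function(vv) shapiro_gate(vv[!is.na(vv)]) >= 0.05))
      fmt <- function(vv) {
        vv <- vv[!is.na(vv)]
        if (normal) sprintf("%.2f (±%.2f)", mean(vv), sd(vv))
        else sprintf("%.2f (%.2f - %.2f)", median(vv), min(vv), max(vv))
      }
      ht <- univariate_group_test(x, g)
      tibble::tibble(variable = v,
                     !!lev[1] := fmt(x[g == lev[1]]),
                     !!lev[2] := fmt(x[g == lev[2]]),
                     test = ht$test, p_value = ht$p_value)
    } else {
      x <- factor(x)
      tab <- table(x, g)
      fmt <- function(col) paste(paste0(rownames(tab), " = ", tab[, col]),
                                 collapse = ", ")
      ht <- if (all(dim(tab) >= 2) && all(rowSums(tab) > 0))
        tryCatch(
          tibble::tibble(test = "chi-square",
                         statistic = unname(chisq.test(tab)$statistic),
                         p_value = chisq.test(tab)$p.value,
                         normality_used = NA),
          error = function(e) tibble::tibble(test = "chi-square",
                                             statistic = NA_real_,
                                             p_value = NA_real_,
                                             normality_used = NA))
      else tibble::tibble(test = "chi-square", statistic = NA_real_,
                          p_value = NA_real_, normality_used = NA)
      tibble::tibble(variable = v,
                     !!lev[1] := fmt(lev[1]),
                     !!lev[2] := fmt(lev[2]),
                     test = ht$test, p_value = ht$p_value)
    }
  })
  dplyr::bind_rows(rows)
}
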