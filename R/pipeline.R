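#' Run configuration for the full analysis pipeline
#'
#' Collects every tunable of the end-to-end analysis in one list.  A
#' configuration can also be read from a YAML file with
#' [read_run_config()].
#'
#' @param cohort_path Optional path to an existing cohort table; when
#'   `NULL` a cohort is generated from `reference` with `seed`.
#' @param reference A `saf_reference_table` (default: the packaged table).
#' @param seed Integer seed; mandatory whenever any stochastic stage runs.
#' @param age_breaks Inclusive upper age-group bounds.
#' @param sr_threshold SR dichotomisation threshold, percent.
#' @param multipliers SD multipliers of the risk scheme.
#' @param effect_factors Factors for confounder-adjusted effect sizes.
#' @param confounders Confounders used for the adjusted effects.
#' @param oplsr_predictors Predictor columns for the per-gender O-PLSR.
#' @param n_ortho Orthogonal components for the O-PLSR.
#' @param n_perm Permutations for O-PLSR validation (0 disables the
#'   permutation stage).
#' @param conventional_scheme Optional path to a YAML scheme to compare
#'   against (see [read_scheme()]).
#' @return A list of class `saf_run_config`.
#' @export
run_config <- function(cohort_path = NULL, reference = saf_reference(),
                       seed = NULL,
                       age_breaks = c(19, 29, 39, 49, 59, 69, 99),
                       sr_threshold = 10, multipliers = c(1, 2),
                       effect_factors = c("gender", "diabetes", "hypertension",
                                          "smoking"),
                       confounders = c("age", "diabetes", "bmi", "sr"),
                       oplsr_predictors = c("age", "height", "weight", "bmi",
                                            "waist", "hip", "whr", "sbp",
                                            "dbp", "sr", "diabetes",
                                            "hypertension", "smoking"),
                       n_ortho = 1, n_perm = 0,
                       conventional_scheme = NULL) {
  structure(list(cohort_path = cohort_path, reference = reference, seed = seed,
                 age_breaks = age_breaks, sr_threshold = sr_threshold,
                 multipliers = multipliers, effect_factors = effect_factors,
                 confounders = confounders, oplsr_predictors = oplsr_predictors,
                 n_ortho = n_ortho, n_perm = n_perm,
                 conventional_scheme = conventional_scheme),
            class = "saf_run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys match the arguments of [run_config()]
#'   (`reference` may be a file path).
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!is.null(doc$reference) && is.character(doc$reference)) {
    doc$reference <- read_reference_table(doc$reference)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(doc), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, doc)
}

.saf_stages <- c("simulate", "reference", "stratify", "effects", "stats", "oplsr")

#' Run the full SAF analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading), reference
#' statistics and curves, risk stratification, confounder-adjusted effect
#' sizes, descriptive statistics and correlations, and per-gender O-PLSR.
#' Identical configuration and seed give byte-identical numeric artifacts
#' (each stochastic stage draws from its own seed derived from the master
#' seed, so disabling one stage leaves the others unchanged).  A stage
#' failure aborts with the stage named in the error.
#'
#' @param config A `saf_run_config`.
#' @param seed Overrides `config$seed`.
#' @param stages Subset of stages to run (`"simulate"` is implied by any
#'   other stage needing the cohort).
#' @return A list of class `saf_report_bundle`: `cohort`, `summary`
#'   (summary tables), `reference` (stratified table + pooled stats),
#'   `curves`, `schemes`, `risk` (assignments + distributions),
#'   `effects`, `correlations`, `oplsr`, and a provenance `manifest`.
#' @examples
#' \donttest{
#' bundle <- run_analysis(run_config(seed = 7))
#' names(bundle)
#' }
#' @export
run_analysis <- function(config, seed = config$seed, stages = .saf_stages) {
  stopifnot(inherits(config, "saf_run_config"))
  stages <- match.arg(stages, .saf_stages, several.ok = TRUE)
  bundle <- list()

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
            parent = e)
    })
  }

  # -- simulate / load -------------------------------------------------
  cohort <- run_stage("simulate", {
    if (!is.null(config$cohort_path)) {
      read_cohort(config$cohort_path)
    } else {
      if (is.null(seed)) abort("a seed is mandatory when generating a cohort")
      generate_cohort(calibrate_generator(config$reference), seed = seed)
    }
  })
  bundle$cohort <- cohort

  if ("stats" %in% stages) {
    bundle$summary <- run_stage("stats", summarize_cohort(
      cohort, by = "gender",
      variables = c("age", "height", "weight", "bmi", "waist", "hip", "whr",
                    "sbp", "dbp", "sr", "saf", "diabetes", "smoking",
                    "exercise")))
    bundle$correlations <- run_stage("stats", list(
      by_gender = correlation_matrix(cohort, split_by = "gender"),
      by_diabetes = correlation_matrix(cohort, split_by = "diabetes")))
  }

  if ("reference" %in% stages) {
    bundle$reference <- run_stage("reference", {
      tab <- compute_stratum_stats(cohort, config$age_breaks, by = "gender")
      list(table = tab, pooled = pool_stats(tab[tab$n > 0, ]))
    })
    bundle$curves <- run_stage("reference", list(
      men = fit_reference_curve(bundle$reference$table, "men", gender = "M"),
      women = fit_reference_curve(bundle$reference$table, "women", gender = "F")))
  }

  if ("stratify" %in% stages) {
    bundle$schemes <- run_stage("stratify", {
      proposed <- fit_risk_scheme(cohort, config$age_breaks,
                                  config$multipliers, config$sr_threshold)
      schemes <- list(proposed = proposed)
      if (!is.null(config$conventional_scheme)) {
        schemes$conventional <- read_scheme(config$conventional_scheme)
      }
      schemes
    })
    bundle$risk <- run_stage("stratify", {
      cmp <- compare_schemes(cohort, bundle$schemes)
      list(assignments = classify_risk(cohort, bundle$schemes$proposed),
           distribution = cmp$distribution, migration = cmp$migration)
    })
  }

  if ("effects" %in% stages) {
    bundle$effects <- run_stage("effects", {
      purrr::map(setNames(config$effect_factors, config$effect_factors),
                 function(f) {
                   conf <- setdiff(config$confounders, f)
                   adjusted_group_effect(cohort, f, conf)
                 }) |> dplyr::bind_rows()
    })
  }

  if ("oplsr" %in% stages) {
    bundle$oplsr <- run_stage("oplsr", {
      purrr::map(setNames(c("M", "F"), c("men", "women")), function(g) {
        sub <- cohort[cohort$gender == g, ]
        preds <- sub[config$oplsr_predictors]
        fit <- fit_oplsr(preds, sub$saf, n_ortho = config$n_ortho)
        cv <- oplsr_cv(preds, sub$saf, n_ortho = config$n_ortho,
                       seed = (seed %||% 1) + 101)
        perm <- if (config$n_perm >= 99) {
          oplsr_permutation(preds, sub$saf, n_ortho = config$n_ortho,
                            n_perm = config$n_perm, seed = (seed %||% 1) + 202)
        }
        list(fit = fit, q2y = cv$q2y, permutation = perm)
      })
    })
  }

  bundle$manifest <- make_manifest(bundle, config, seed)
  structure(bundle, class = "saf_report_bundle")
}

make_manifest <- function(bundle, config, seed) {
  numeric_artifacts <- bundle[setdiff(names(bundle), "manifest")]
  list(seed = seed,
       package_version = as.character(utils::packageVersion("safref")),
       stages = setdiff(names(numeric_artifacts), "cohort"),
       config_hash = rlang::hash(config[setdiff(names(config), "reference")]),
       artifact_hash = rlang::hash(numeric_artifacts))
}

#' Write a report bundle to disk
#'
#' Emits every tabular artifact as delimited text (or JSON), a
#' human-readable `summary.txt`, and (optionally) the standard figures:
#' reference curves with risk bands, risk-group distribution bars, and
#' O-PLSR score/loading plots.
#'
#' @param bundle A `saf_report_bundle` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"json"` for the tables.
#' @param plots Write PDF figures as well?
#' @return Invisibly, the paths written.
#' @export
render_report <- function(bundle, dir, format = "tsv", plots = FALSE) {
  stopifnot(inherits(bundle, "saf_report_bundle"))
  if (!format %in% c("tsv", "json")) {
    abort(paste0("unknown format '", format, "'; supported: tsv, json"))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(x, name) {
    p <- file.path(dir, paste0(name, ".", format))
    if (format == "tsv") {
      readr::write_tsv(tibble::as_tibble(x), p)
    } else {
      jsonlite::write_json(x, p, digits = NA, pretty = TRUE)
    }
    paths <<- c(paths, p)
  }
  emit(bundle$cohort, "cohort")
  if (!is.null(bundle$summary)) emit(bundle$summary, "summary_table")
  if (!is.null(bundle$reference)) {
    emit(unclass_tbl(bundle$reference$table), "reference_table")
    emit(bundle$reference$pooled, "pooled_stats")
  }
  if (!is.null(bundle$curves)) {
    emit(dplyr::bind_rows(purrr::imap(bundle$curves, function(c, nm) {
      dplyr::mutate(tidy(c), stratum = nm, .before = 1)
    })), "reference_curves")
  }
  if (!is.null(bundle$schemes)) {
    for (nm in names(bundle$schemes)) {
      p <- file.path(dir, paste0("scheme_", nm, ".yaml"))
      write_scheme(bundle$schemes[[nm]], p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(bundle$risk)) {
    emit(bundle$risk$distribution, "risk_distribution")
    if (!is.null(bundle$risk$migration)) emit(bundle$risk$migration, "risk_migration")
  }
  if (!is.null(bundle$effects)) emit(unclass_tbl(bundle$effects), "effect_sizes")
  if (!is.null(bundle$correlations)) {
    emit(tidy(bundle$correlations$by_gender), "correlations_gender")
    emit(tidy(bundle$correlations$by_diabetes), "correlations_diabetes")
  }
  if (!is.null(bundle$oplsr)) {
    emit(dplyr::bind_rows(purrr::imap(bundle$oplsr, function(m, nm) {
      dplyr::mutate(glance(m$fit), q2y = m$q2y, gender = nm, .before = 1)
    })), "oplsr_summary")
    emit(dplyr::bind_rows(purrr::imap(bundle$oplsr, function(m, nm) {
      dplyr::mutate(tidy(m$fit), gender = nm, .before = 1)
    })), "oplsr_loadings")
  }
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(bundle$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  paths <- c(paths, manifest_path)
  writeLines(report_summary_text(bundle), file.path(dir, "summary.txt"))
  paths <- c(paths, file.path(dir, "summary.txt"))
  if (plots) {
    save_plot <- function(p, name, w = 8, h = 5) {
      fp <- file.path(dir, paste0(name, ".pdf"))
      grDevices::pdf(fp, width = w, height = h)
      print(p)
      grDevices::dev.off()
      paths <<- c(paths, fp)
    }
    if (!is.null(bundle$schemes$proposed)) {
      save_plot(autoplot(bundle$schemes$proposed, bundle$cohort), "risk_bands")
    }
    if (!is.null(bundle$risk)) {
      save_plot(
        ggplot(bundle$risk$distribution,
               aes(x = .data$group, y = .data$pct, fill = .data$scheme)) +
          geom_col(position = "dodge") + facet_wrap(~stratum) +
          labs(x = "Risk group", y = "% of stratum"),
        "risk_distribution")
    }
    if (!is.null(bundle$oplsr)) {
      for (nm in names(bundle$oplsr)) {
        save_plot(autoplot(bundle$oplsr[[nm]]$fit), paste0("oplsr_scores_", nm))
        save_plot(plot_oplsr_loadings(bundle$oplsr[[nm]]$fit),
                  paste0("oplsr_loadings_", nm))
      }
    }
  }
  invisible(paths)
}

report_summary_text <- function(bundle) {
  lines <- c("SAF reference and risk stratification report",
             paste0("seed: ", bundle$manifest$seed,
                    "; artifact hash: ", bundle$manifest$artifact_hash),
             paste0("subjects: ", nrow(bundle$cohort)))
  if (!is.null(bundle$reference)) {
    p <- bundle$reference$pooled
    lines <- c(lines, sprintf("pooled SAF: %.2f (SD %.2f) AU over %d subjects",
                              p$grand_mean, p$grand_sd, p$n_total))
  }
  if (!is.null(bundle$risk)) {
    d <- bundle$risk$distribution
    d <- d[d$scheme == d$scheme[1], ]
    lines <- c(lines, "risk-group distribution (proposed scheme):",
               utils::capture.output(print.data.frame(as.data.frame(d))))
  }
  if (!is.null(bundle$oplsr)) {
    for (nm in names(bundle$oplsr)) {
      m <- bundle$oplsr[[nm]]
      lines <- c(lines, sprintf("O-PLSR %s: R2X %.3f R2Y %.3f Q2Y %.3f", nm,
                                m$fit$r2x, m$fit$r2y, m$q2y))
    }
  }
  lines
}

#' @export
print.saf_report_bundle <- function(x, ...) {
  cat(report_summary_text(x), sep = "\n")
  invisible(x)
}
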