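#' Read and write subject-level cohort tables
#'
#' Cohorts are plain delimited tables (UTF-8, `.` decimal separator, header
#' row, empty string for missing) with one row per subject.  The delimiter
#' is inferred from the extension: `.csv` is comma-delimited, anything else
#' tab-delimited.  A write/read round trip is the identity on all fields;
#' columns beyond the documented schema are preserved untouched.
#'
#' Mandatory columns are `id`, `gender`, `age`, `sr` and `saf`; `age`, `sr`
#' and `saf` must parse as numbers.  Rows with `sr` below the measurability
#' floor (6% — below it no valid SAF reading exists) are kept but flagged:
#' a logical `valid_sr` column is added and a warning raised.
#'
#' @param path File path.
#' @param cohort A cohort tibble (e.g. from [generate_cohort()]).
#' @param sr_min Minimum measurable skin reflectance, percent.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path, sr_min = 6) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  # read as text and convert with base R parsers: exact double round trip
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, na = "",
                         col_types = readr::cols(.default = readr::col_character()))
  mandatory <- c("id", "gender", "age", "sr", "saf")
  miss <- setdiff(mandatory, names(x))
  if (length(miss) > 0) {
    abort(paste0("cohort schema error: missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  numeric_cols <- intersect(c("age", "sr", "saf", "height", "weight", "bmi",
                              "waist", "hip", "whr", "sbp", "dbp"), names(x))
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(!is.na(x[[col]]) & is.na(parsed))
    if (length(bad) > 0) {
      abort(paste0("cohort parse error: column '", col,
                   "' is not numeric (first offending row: ", bad[1], ")"))
    }
    x[[col]] <- parsed
  }
  if (all(x$age == round(x$age), na.rm = TRUE)) x$age <- as.integer(x$age)
  for (col in intersect(c("diabetes", "hypertension", "smoking", "valid_sr"),
                        names(x))) {
    x[[col]] <- as.logical(x[[col]])
  }
  extras <- setdiff(names(x), c(mandatory, numeric_cols, "nationality",
                                "exercise", "diabetes", "hypertension",
                                "smoking", "valid_sr"))
  for (col in extras) {
    x[[col]] <- readr::parse_guess(x[[col]], na = "")
  }
  x$id <- as.character(x$id)
  if ("exercise" %in% names(x) &&
      all(stats::na.omit(x$exercise) %in% .exercise_levels)) {
    x$exercise <- factor(x$exercise, levels = .exercise_levels, ordered = TRUE)
  }
  low <- which(!is.na(x$sr) & x$sr < sr_min)
  if (length(low) > 0) {
    warn(paste0(length(low), " row(s) have SR below ", sr_min,
                "% (no valid SAF measurement); flagged in 'valid_sr'"))
    x$valid_sr <- is.na(x$sr) | x$sr >= sr_min
  }
  x
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  # 17 significant digits make the double round trip exact
  out <- dplyr::mutate(tibble::as_tibble(cohort), dplyr::across(
    dplyr::where(is.double),
    ~ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))))
  readr::write_delim(out, path, delim = delim, na = "")
  invisible(path)
}
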