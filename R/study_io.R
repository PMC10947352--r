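#' Canonical study-table columns
#'
#' Column names of the study-level CSV schema: one study arm per row, empty
#' cell meaning "not reported". `study_id`, `group` and `n` are mandatory; at
#' least one AL location summary column (`al_mean` or `al_median`) and one age
#' location summary column must exist in the file.
#'
#' @return Character vector of column names in canonical order.
#' @export
study_csv_columns <- function() {
  c("study_id", "region", "group", "n",
    "age_mean", "age_sd", "age_median", "age_q1", "age_q3", "age_min", "age_max",
    "age_is_whole_sample", "whole_sample_age_range",
    "al_mean", "al_sd", "al_median", "al_q1", "al_q3", "al_min", "al_max",
    "ser_lower", "ser_upper", "cycloplegia", "biometry", "prop_male")
}

study_numeric_columns <- function() {
  setdiff(study_csv_columns(),
          c("study_id", "region", "group", "biometry",
            "age_is_whole_sample", "cycloplegia"))
}

# parse a numeric column that may use the Unicode minus sign (U+2212);
# errors name the row index of the first unparseable cell
parse_signed_numeric <- function(x, col) {
  x <- trimws(as.character(x))
  x <- gsub("−", "-", x)
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("Column '%s': unparseable numeric value '%s' in row %d.",
                  col, x[bad[1]], bad[1]))
  }
  out
}

parse_flag <- function(x, col) {
  x <- trimws(tolower(as.character(x)))
  x[x == ""] <- NA_character_
  out <- dplyr::case_match(x, c("1", "true", "yes") ~ TRUE,
                           c("0", "false", "no") ~ FALSE,
                           .default = NA)
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    abort(sprintf("Column '%s': unparseable flag '%s' in row %d (use 0/1).",
                  col, x[bad[1]], bad[1]))
  }
  out
}

#' Read a study-level summary table
#'
#' Reads the study CSV schema (see [study_csv_columns]) into a tibble. Missing
#' optional summaries are `NA`, never zero. Signed dioptre columns accept both
#' the ASCII hyphen and the Unicode minus sign. Reported AL means outside
#' 18–28 mm or age means outside 0–40 years are rejected as likely unit
#' errors.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A tibble with one row per study arm and the canonical columns
#'   (missing optional columns are added as `NA`).
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  mandatory <- c("study_id", "group", "n")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("Schema error: missing mandatory column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (!any(c("al_mean", "al_median") %in% names(raw))) {
    abort("Schema error: missing mandatory column(s): al_mean or al_median (an emmetrope-specific AL summary is required).")
  }
  if (!any(c("age_mean", "age_median") %in% names(raw))) {
    abort("Schema error: missing mandatory column(s): age_mean or age_median.")
  }
  for (col in setdiff(study_csv_columns(), names(raw))) raw[[col]] <- NA_character_

  df <- tibble::tibble(
    study_id = as.character(raw$study_id),
    region = as.character(raw$region),
    group = as.character(raw$group)
  )
  for (col in study_numeric_columns()) df[[col]] <- parse_signed_numeric(raw[[col]], col)
  df$age_is_whole_sample <- parse_flag(raw$age_is_whole_sample, "age_is_whole_sample")
  df$age_is_whole_sample[is.na(df$age_is_whole_sample)] <- FALSE
  df$cycloplegia <- parse_flag(raw$cycloplegia, "cycloplegia")
  df$biometry <- as.character(raw$biometry)
  df <- df[, study_csv_columns()]

  bad_group <- which(!is.na(df$group) & !df$group %in% c("EA", "nonEA"))
  if (length(bad_group) > 0) {
    abort(sprintf("Column 'group': unknown label '%s' in row %d (use EA or nonEA).",
                  df$group[bad_group[1]], bad_group[1]))
  }
  validate_plausibility(df)
  df
}

# AL window [18, 28] mm and age window [0, 40] yr reject unit errors (e.g. cm)
validate_plausibility <- function(df) {
  bad_al <- which(!is.na(df$al_mean) & (df$al_mean < 18 | df$al_mean > 28))
  if (length(bad_al) > 0) {
    abort(sprintf("Implausible AL mean %.4g mm (outside 18-28 mm) for study '%s'; check units.",
                  df$al_mean[bad_al[1]], df$study_id[bad_al[1]]))
  }
  bad_age <- which(!is.na(df$age_mean) & (df$age_mean < 0 | df$age_mean > 40))
  if (length(bad_age) > 0) {
    abort(sprintf("Implausible age mean %.4g years (outside 0-40) for study '%s'.",
                  df$age_mean[bad_age[1]], df$study_id[bad_age[1]]))
  }
  invisible(df)
}

#' Write a study-level summary table
#'
#' Inverse of [read_studies]: writes the canonical columns as CSV with empty
#' cells for `NA` and 0/1 flags, so that write-then-read is the identity.
#'
#' @param studies Tibble of study records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path) {
  out <- studies[, intersect(study_csv_columns(), names(studies))]
  out$age_is_whole_sample <- as.integer(out$age_is_whole_sample)
  out$cycloplegia <- as.integer(out$cycloplegia)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Impute a mean and SD from reported summary statistics
#'
#' When a study reports a median with an interquartile range and/or a range
#' instead of a mean and SD, estimates both using the sample-size-adjusted
#' normal-quantile formulas of Wan et al. (2014, BMC Med Res Methodol 14:135):
#' \itemize{
#'   \item median + range: `mean = (min + 2*median + max) / 4`,
#'     `sd = (max - min) / (2 * qnorm((n - 0.375) / (n + 0.25)))`;
#'   \item median + IQR: `mean = (q1 + median + q3) / 3`,
#'     `sd = (q3 - q1) / (2 * qnorm((0.75n - 0.125) / (n + 0.25)))`;
#'   \item all five numbers: `mean = (min + 2*q1 + 2*median + 2*q3 + max) / 8`,
#'     `sd` = the average of the two SD estimators.
#' }
#' Fully reported records pass through unchanged (the operation is
#' idempotent).
#'
#' @param n Sample size (vectorised with the other arguments).
#' @param mean,sd Reported mean and SD, or `NA`.
#' @param median,q1,q3,min,max Reported order statistics, or `NA`.
#' @return A tibble with columns `mean`, `sd` and `method` (one of
#'   `"reported"`, `"median_range"`, `"median_iqr"`, `"median_iqr_range"`).
#' @references Wan X, Wang W, Liu J, Tong T (2014). Estimating the sample mean
#'   and standard deviation from the sample size, median, range and/or
#'   interquartile range. BMC Medical Research Methodology 14:135.
#' @examples
#' impute_mean_sd(n = 100, median = 10, q1 = 8, q3 = 12)
#' @export
impute_mean_sd <- function(n, mean = NA, sd = NA, median = NA,
                           q1 = NA, q3 = NA, min = NA, max = NA) {
  args <- vctrs_recycle(n = n, mean = mean, sd = sd, median = median,
                        q1 = q1, q3 = q3, min = min, max = max)
  purrr::pmap(args, impute_mean_sd_one) |> dplyr::bind_rows()
}

vctrs_recycle <- function(...) {
  args <- lapply(list(...), as.numeric)
  len <- max(lengths(args))
  lapply(args, rep_len, length.out = len)
}

impute_mean_sd_one <- function(n, mean, sd, median, q1, q3, min, max) {
  if (is.na(n) || n < 1) abort("`n` must be a positive count.")
  if (!is.na(mean) && !is.na(sd)) {
    if (sd < 0) abort("Reported `sd` must be non-negative.")
    return(tibble::tibble(mean = mean, sd = sd, method = "reported"))
  }
  has_iqr <- !is.na(median) && !is.na(q1) && !is.na(q3)
  has_range <- !is.na(median) && !is.na(min) && !is.na(max)
  if (!has_iqr && !has_range) {
    missing <- c(
      if (is.na(mean)) "mean", if (is.na(sd)) "sd",
      if (is.na(median)) "median",
      if (is.na(q1) || is.na(q3)) "q1/q3",
      if (is.na(min) || is.na(max)) "min/max"
    )
    abort(sprintf(
      "Cannot impute mean/sd: need mean+sd, or median with IQR and/or range; missing: %s.",
      paste(missing, collapse = ", ")))
  }
  if (n < 2) abort("Cannot impute sd from spread statistics with n < 2.")
  check_order(min, q1, median, q3, max)
  sd_range <- if (has_range) (max - min) / (2 * qnorm((n - 0.375) / (n + 0.25)))
  sd_iqr <- if (has_iqr) (q3 - q1) / (2 * qnorm((0.75 * n - 0.125) / (n + 0.25)))
  if (has_iqr && has_range) {
    tibble::tibble(mean = (min + 2 * q1 + 2 * median + 2 * q3 + max) / 8,
                   sd = (sd_range + sd_iqr) / 2, method = "median_iqr_range")
  } else if (has_iqr) {
    tibble::tibble(mean = (q1 + median + q3) / 3, sd = sd_iqr,
                   method = "median_iqr")
  } else {
    tibble::tibble(mean = (min + 2 * median + max) / 4, sd = sd_range,
                   method = "median_range")
  }
}

check_order <- function(min, q1, median, q3, max) {
  vals <- c(min, q1, median, q3, max)
  present <- !is.na(vals)
  if (is.unsorted(vals[present])) {
    abort("Order statistics violate min <= q1 <= median <= q3 <= max.")
  }
  invisible(TRUE)
}

#' Fill in missing means and SDs across a study table
#'
#' Applies [impute_mean_sd] to the age and AL summaries of every study,
#' filling `age_mean`/`age_sd`/`al_mean`/`al_sd` where absent and recording
#' the method used in `age_method` and `al_method`.
#'
#' @param studies Tibble in the [study_csv_columns] schema.
#' @param strict If `TRUE` (default), a study whose summaries are insufficient
#'   for imputation is an error; if `FALSE`, its mean/sd are left `NA` with
#'   method `"insufficient"` (used by the screening pipeline, where a missing
#'   AL summary is an ineligibility reason rather than an error).
#' @return The input tibble with completed means/SDs plus the two method
#'   columns.
#' @export
impute_summaries <- function(studies, strict = TRUE) {
  impute <- if (strict) impute_mean_sd else impute_mean_sd_lenient
  age <- impute(studies$n, studies$age_mean, studies$age_sd,
                studies$age_median, studies$age_q1, studies$age_q3,
                studies$age_min, studies$age_max)
  al <- impute(studies$n, studies$al_mean, studies$al_sd,
               studies$al_median, studies$al_q1, studies$al_q3,
               studies$al_min, studies$al_max)
  out <- studies |>
    dplyr::mutate(age_mean = age$mean, age_sd = age$sd, age_method = age$method,
                  al_mean = al$mean, al_sd = al$sd, al_method = al$method)
  validate_plausibility(out)
  out
}

impute_mean_sd_lenient <- function(n, mean, sd, median, q1, q3, min, max) {
  args <- vctrs_recycle(n = n, mean = mean, sd = sd, median = median,
                        q1 = q1, q3 = q3, min = min, max = max)
  purrr::pmap(args, function(...) {
    tryCatch(impute_mean_sd_one(...),
             error = function(e) tibble::tibble(mean = NA_real_, sd = NA_real_,
                                                method = "insufficient"))
  }) |> dplyr::bind_rows()
}
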