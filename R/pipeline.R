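# write the run manifest that accompanies every pipeline output
write_manifest <- function(dir, command, seed, config, paths) {
  manifest <- list(
    command = command,
    seed = seed,
    config = config,
    paths = paths,
    package_version = as.character(utils::packageVersion("algrowth")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Screen a study table and write a report
#'
#' Reads a study CSV, applies [screen_studies], and writes a per-study
#' decision report (`study_id`, `eligible`, `reason`) plus a run manifest
#' containing the summary count per reason code.
#'
#' @param input Path to a study CSV in the [study_csv_columns] schema.
#' @param output Path for the report CSV.
#' @param criteria A [screening_criteria] object.
#' @return Invisibly, a list with `report` (the decision tibble) and
#'   `summary` (a tibble of counts per reason code).
#' @export
run_screen <- function(input, output, criteria = screening_criteria()) {
  studies <- read_studies(input)
  report <- screen_studies(studies, criteria)
  readr::write_csv(report, output)
  summary <- dplyr::count(report, .data$reason, name = "n_studies")
  write_manifest(dirname(output), "screen", seed = NULL,
                 config = unclass(criteria),
                 paths = list(input = input, output = output,
                              summary = as.list(setNames(summary$n_studies,
                                                         summary$reason))))
  invisible(list(report = report, summary = summary))
}

#' Run the full meta-regression pipeline
#'
#' Screen, impute, weight and fit: eligible studies are imputed
#' ([impute_summaries]), precision-weighted ([add_weights], normalising over
#' the fitted cohort), fitted combined and (optionally) with the two-level
#' ethnicity grouping, Wald contrasts are tested, and an age-specific growth
#' table is produced. Outputs written to `output_dir`: `fit.json` (parameter
#' estimates, covariance, variance components, trace), `growth_table.csv`,
#' `report.txt` and a run manifest. Deterministic given `seed` (timestamps
#' live only in the manifest).
#'
#' @param input Path to a study CSV.
#' @param output_dir Output directory (created if needed).
#' @param seed Seed passed to the optimiser's multi-start jitter.
#' @param groups Also fit the grouped model and test contrasts?
#' @param random_effects Passed to [fit_al_growth].
#' @param starts Multi-start count.
#' @param ages Ages for the growth table.
#' @param criteria Screening criteria.
#' @return Invisibly, a list with `combined`, `grouped` (or `NULL`),
#'   `contrasts` (or `NULL`) and `table`.
#' @export
run_fit <- function(input, output_dir, seed = 1L, groups = TRUE,
                    random_effects = TRUE, starts = 8, ages = 6:24,
                    criteria = screening_criteria()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  studies <- read_studies(input)
  decisions <- screen_studies(studies, criteria)
  eligible <- studies[decisions$eligible, ]
  if (nrow(eligible) < 3) {
    abort(sprintf("Only %d eligible studies after screening; need at least 3.",
                  nrow(eligible)), class = "algrowth_screening_empty")
  }
  obs <- eligible |> impute_summaries() |> add_weights()

  combined <- fit_al_growth(obs, grouped = FALSE,
                            random_effects = random_effects,
                            starts = starts, seed = seed)
  grouped_fit <- NULL
  contrasts <- NULL
  if (groups) {
    grouped_fit <- fit_al_growth(obs, grouped = TRUE,
                                 random_effects = random_effects,
                                 starts = starts, seed = seed)
    contrasts <- wald_contrasts(grouped_fit)
  }
  if (!combined$converged || (groups && !grouped_fit$converged)) {
    abort("Estimation did not converge; see the optimiser trace in fit.json.",
          class = "algrowth_nonconvergence")
  }

  tbl <- if (groups) {
    dplyr::bind_rows(growth_table(combined, ages),
                     growth_table(grouped_fit, ages))
  } else growth_table(combined, ages)
  readr::write_csv(format_growth_table(tbl), file.path(output_dir, "growth_table.csv"))

  fits_json <- list(combined = fit_to_list(combined),
                    grouped = if (groups) fit_to_list(grouped_fit),
                    contrasts = if (groups) contrasts)
  jsonlite::write_json(fits_json, file.path(output_dir, "fit.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")

  report <- c(
    sprintf("Studies read: %d; eligible: %d", nrow(studies), nrow(eligible)),
    sprintf("Combined curve: AL = %.2f + (%.2f) * exp(-%.2f * age)",
            combined$parameters[[1]], combined$parameters[[2]],
            combined$parameters[[3]]),
    if (groups) paste0(contrasts$name, ": ", format_wald(contrasts)))
  writeLines(report, file.path(output_dir, "report.txt"))

  write_manifest(output_dir, "fit", seed = seed,
                 config = list(groups = groups, random_effects = random_effects,
                               starts = starts, ages = range(ages),
                               criteria = unclass(criteria)),
                 paths = list(input = input, output_dir = output_dir))
  invisible(list(combined = combined, grouped = grouped_fit,
                 contrasts = contrasts, table = tbl))
}

fit_to_list <- function(fit) {
  list(parameters = as.list(fit$parameters),
       se = as.list(setNames(sqrt(diag(fit$vcov)), names(fit$parameters))),
       covariance = unname(apply(fit$vcov, 1, as.list)),
       sigma2 = fit$sigma2, tau2 = fit$tau2,
       tau2_boundary = fit$tau2_boundary,
       loglik = fit$loglik, aic = fit$aic, converged = fit$converged,
       n_studies = fit$n_studies, grouped = fit$grouped,
       reference = fit$reference, method = fit$method, seed = fit$seed,
       trace = fit$trace)
}

#' Simulate a corpus and write it as a study CSV
#'
#' @param config A [synthetic_config], or a path to a YAML file for
#'   [synthetic_config_from_yaml].
#' @param output Path for the corpus CSV (written in the study-table schema).
#' @return Invisibly, the simulated study tibble.
#' @export
run_simulate <- function(config = synthetic_config(), output) {
  if (is.character(config)) config <- synthetic_config_from_yaml(config)
  studies <- simulate_corpus(config)
  write_studies(studies, output)
  cfg <- unclass(config)
  cfg$true_params <- purrr::map(cfg$true_params, unclass)
  write_manifest(dirname(output), "simulate", seed = config$seed,
                 config = cfg, paths = list(output = output))
  invisible(studies)
}
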