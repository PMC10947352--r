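#' Configuration for the synthetic study-corpus generator
#'
#' Describes a corpus of study-level records built from simulated individual
#' eyes: each study draws a mean-age centre, a study-level random intercept on
#' the asymptote, and per-eye ages and axial lengths around its group's true
#' growth curve, then summarises them the way primary studies report
#' (mean+SD, median+IQR or median+range). Defaults emulate the published
#' corpus: 16 East-Asian and 12 non-East-Asian study arms, study sizes 20-600
#' eyes, mean ages spanning 6.5-23.1 years, and the published ethnic-specific
#' curves as truth.
#'
#' @param true_params Named list of [growth_params] per group (`EA`,
#'   `nonEA`).
#' @param n_studies_per_group Named integer vector: studies per group.
#' @param study_size_range Length-2 integer: smallest and largest study size
#'   (eyes); sizes are drawn log-uniformly, mimicking the right-skewed sizes
#'   of real study arms.
#' @param age_center_range Length-2 numeric: range of study mean-age centres
#'   (years).
#' @param within_study_age_sd SD of individual ages around the study centre
#'   (years).
#' @param between_study_sd SD of the study-level random intercept on the
#'   asymptote (mm).
#' @param individual_al_sd SD of individual AL around the study's curve (mm).
#' @param reporting_style How records summarise their eyes: `"mean_sd"`,
#'   `"median_iqr"` or `"median_range"`.
#' @param seed Integer seed; the corpus is reproducible from it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(true_params = list(
                               EA = growth_params(23.69, -6.91, 0.33),
                               nonEA = growth_params(23.54, -4.15, 0.24)),
                             n_studies_per_group = c(EA = 16L, nonEA = 12L),
                             study_size_range = c(20L, 600L),
                             age_center_range = c(6.5, 23.1),
                             within_study_age_sd = 1.0,
                             between_study_sd = 0.2,
                             individual_al_sd = 0.6,
                             reporting_style = c("mean_sd", "median_iqr",
                                                 "median_range"),
                             seed = 1L) {
  reporting_style <- match.arg(reporting_style)
  stopifnot(all(c("EA", "nonEA") %in% names(true_params)),
            all(purrr::map_lgl(true_params, inherits, "growth_params")),
            study_size_range[1] >= 2, study_size_range[1] <= study_size_range[2],
            age_center_range[1] >= 0, age_center_range[2] <= 40,
            within_study_age_sd >= 0, between_study_sd >= 0,
            individual_al_sd >= 0)
  structure(list(true_params = true_params,
                 n_studies_per_group = n_studies_per_group,
                 study_size_range = study_size_range,
                 age_center_range = age_center_range,
                 within_study_age_sd = within_study_age_sd,
                 between_study_sd = between_study_sd,
                 individual_al_sd = individual_al_sd,
                 reporting_style = reporting_style,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Read a synthetic-data configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror the arguments of
#'   [synthetic_config]; `true_params` entries are `a`/`b`/`c` maps.
#' @return A `synthetic_config` object.
#' @export
synthetic_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("Package 'yaml' is required to read YAML configs.")
  }
  y <- yaml::read_yaml(path)
  defaults <- synthetic_config()
  if (!is.null(y$true_params)) {
    y$true_params <- purrr::map(y$true_params,
                                ~ growth_params(.x$a, .x$b, .x$c))
  }
  if (!is.null(y$n_studies_per_group)) {
    y$n_studies_per_group <- unlist(y$n_studies_per_group)
  }
  args <- modifyList(unclass(defaults), y)
  do.call(synthetic_config, args)
}

# ages truncated to >= 0 by resampling (no point mass at zero)
draw_ages <- function(n, center, sd) {
  ages <- rnorm(n, center, sd)
  while (any(ages < 0)) {
    bad <- ages < 0
    ages[bad] <- rnorm(sum(bad), center, sd)
  }
  ages
}

#' Simulate one study arm
#'
#' Draws a study mean-age centre uniformly over `age_center_range`, a study
#' intercept `u ~ N(0, between_study_sd^2)` shifting the whole curve, then
#' per-eye ages `~ N(centre, within_study_age_sd^2)` (truncated at 0 by
#' resampling) and axial lengths `curve(age) + u + N(0, individual_al_sd^2)`.
#' The returned record summarises the eyes per the configured reporting
#' style. Uses the current RNG state; seed via [simulate_corpus] or
#' `set.seed` for reproducibility.
#'
#' @param config A [synthetic_config].
#' @param group `"EA"` or `"nonEA"`.
#' @param study_id Identifier for the record.
#' @param center Optional study mean-age centre (years); drawn uniformly over
#'   `age_center_range` when `NULL`. [simulate_corpus] supplies stratified
#'   centres so every corpus spans the configured mean-age range, like the
#'   published corpus.
#' @return A list with `eyes` (tibble: `study_id`, `group`, `age`, `al`) and
#'   `record` (a one-row tibble in the [study_csv_columns] schema).
#' @export
simulate_study <- function(config, group, study_id = paste0(group, "_1"),
                           center = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  group <- match.arg(group, c("EA", "nonEA"))
  params <- config$true_params[[group]]
  n <- round(exp(runif(1, log(config$study_size_range[1]),
                       log(config$study_size_range[2]))))
  center <- center %||%
    runif(1, config$age_center_range[1], config$age_center_range[2])
  u <- rnorm(1, 0, config$between_study_sd)
  ages <- draw_ages(n, center, config$within_study_age_sd)
  al <- predict_al(params, ages) + u + rnorm(n, 0, config$individual_al_sd)
  eyes <- tibble::tibble(study_id = study_id, group = group, age = ages, al = al)

  rec <- tibble::tibble(
    study_id = study_id, region = "synthetic", group = group, n = n,
    age_mean = NA_real_, age_sd = NA_real_, age_median = NA_real_,
    age_q1 = NA_real_, age_q3 = NA_real_, age_min = NA_real_,
    age_max = NA_real_, age_is_whole_sample = FALSE,
    whole_sample_age_range = NA_real_,
    al_mean = NA_real_, al_sd = NA_real_, al_median = NA_real_,
    al_q1 = NA_real_, al_q3 = NA_real_, al_min = NA_real_, al_max = NA_real_,
    ser_lower = -0.50, ser_upper = 0.50, cycloplegia = TRUE,
    biometry = "optical", prop_male = NA_real_)
  if (config$reporting_style == "mean_sd") {
    rec$age_mean <- mean(ages); rec$age_sd <- stats::sd(ages)
    rec$al_mean <- mean(al); rec$al_sd <- stats::sd(al)
  } else if (config$reporting_style == "median_iqr") {
    qa <- quantile(ages, c(0.25, 0.5, 0.75), names = FALSE)
    ql <- quantile(al, c(0.25, 0.5, 0.75), names = FALSE)
    rec$age_q1 <- qa[1]; rec$age_median <- qa[2]; rec$age_q3 <- qa[3]
    rec$al_q1 <- ql[1]; rec$al_median <- ql[2]; rec$al_q3 <- ql[3]
  } else {
    rec$age_median <- median(ages); rec$age_min <- min(ages); rec$age_max <- max(ages)
    rec$al_median <- median(al); rec$al_min <- min(al); rec$al_max <- max(al)
  }
  list(eyes = eyes, record = rec)
}

#' Simulate a full study corpus
#'
#' Generates `n_studies_per_group` records per group, reproducibly from the
#' config's seed (the caller's RNG state is preserved). Each record is
#' guaranteed to pass [screen_studies] under the default criteria: in the
#' rare event a draw lands outside the eligible mean-age window, the study is
#' redrawn.
#'
#' @param config A [synthetic_config].
#' @param individuals If `TRUE`, also return the individual eyes.
#' @return A tibble of study records, or (with `individuals = TRUE`) a list
#'   with `studies` and `eyes`.
#' @export
simulate_corpus <- function(config = synthetic_config(), individuals = FALSE) {
  stopifnot(inherits(config, "synthetic_config"))
  criteria <- screening_criteria()
  with_preserved_seed(config$seed, {
    records <- list(); eyes <- list()
    for (group in names(config$n_studies_per_group)) {
      ng <- config$n_studies_per_group[[group]]
      if (ng > 0 && !group %in% c("EA", "nonEA")) {
        abort(sprintf("Unknown group '%s' in n_studies_per_group.", group))
      }
      # stratified mean-age centres: one per equal-width stratum of the
      # configured range (shuffled), so each group's studies span it the way
      # the source corpus's mean ages span 6.5-23.1 years
      rng <- config$age_center_range
      centers <- sample(rng[1] + (seq_len(ng) - runif(ng)) *
                          diff(rng) / ng)
      for (j in seq_len(ng)) {
        id <- sprintf("%s_%02d", group, j)
        for (attempt in 1:50) {
          sim <- simulate_study(config, group, id, center = centers[j])
          ok <- tryCatch(screen_studies(sim$record, criteria)$eligible,
                         error = function(e) FALSE)
          if (isTRUE(ok)) break
        }
        records[[id]] <- sim$record
        eyes[[id]] <- sim$eyes
      }
    }
    if (length(records) == 0) {
      warn("Empty corpus: n_studies_per_group is all zero.")
      studies <- tibble::as_tibble(
        sapply(study_csv_columns(), function(x) logical(0),
               simplify = FALSE))[0, ]
      return(if (individuals) list(studies = studies,
                                   eyes = tibble::tibble()) else studies)
    }
    studies <- dplyr::bind_rows(records)
    if (individuals) list(studies = studies, eyes = dplyr::bind_rows(eyes))
    else studies
  })
}
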