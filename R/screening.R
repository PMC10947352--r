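#' Screening criteria
#'
#' Eligibility rules for the meta-regression: AL measured with non-contact
#' optical biometry; the study's emmetropia definition (SER window, dioptres)
#' contained in `ser_window`; refraction under cycloplegia unless the mean age
#' is at least `noncyclo_min_age` years; mean age within `age_range`; and an
#' emmetrope-specific AL summary present.
#'
#' @param ser_window Length-2 numeric, the widest acceptable emmetropia
#'   definition in dioptres (default -0.50 to +1.25 D). A study is eligible
#'   only if its own SER window lies inside this one.
#' @param noncyclo_min_age Minimum mean age (years) at which non-cycloplegic
#'   refraction is acceptable (default 20; "20 years or older").
#' @param age_range Acceptable mean-age window in years (default 6 to 30).
#' @return A list of class `screening_criteria`.
#' @export
screening_criteria <- function(ser_window = c(-0.50, 1.25),
                               noncyclo_min_age = 20,
                               age_range = c(6, 30)) {
  stopifnot(length(ser_window) == 2, ser_window[1] < ser_window[2],
            length(age_range) == 2, age_range[1] < age_range[2])
  structure(list(ser_window = ser_window, noncyclo_min_age = noncyclo_min_age,
                 age_range = age_range), class = "screening_criteria")
}

#' Resolve the age summary of each study
#'
#' Emmetrope-specific age summaries are used as-is. Where a study only reports
#' the whole sample's age, it is accepted as a stand-in on the condition that
#' the whole-sample age range is no larger than 3 years; otherwise (or when
#' the range is unreported, so the condition cannot be verified) the record is
#' refused with reason `age_imputation_refused`.
#'
#' @param studies Tibble in the [study_csv_columns] schema.
#' @param max_whole_sample_range Largest acceptable whole-sample age range in
#'   years (default 3).
#' @return The input with a logical `age_resolved` column.
#' @export
resolve_age <- function(studies, max_whole_sample_range = 3) {
  studies |>
    dplyr::mutate(age_resolved = !.data$age_is_whole_sample |
                    (!is.na(.data$whole_sample_age_range) &
                       .data$whole_sample_age_range <= max_whole_sample_range))
}

#' Screen studies against the eligibility rules
#'
#' Applies the rules of [screening_criteria] in a fixed order so reason codes
#' are reproducible: (1) optical biometry (any other AL measurement, e.g.
#' ultrasonography, gives `ultrasound_al`); (2) the study's SER window inside
#' the emmetropia window (`ser_window_violation`); (3) a usable age summary
#' per [resolve_age] (`age_imputation_refused`; checked here because the
#' remaining rules need a trusted age); (4) cycloplegia unless mean age >=
#' `noncyclo_min_age` (`noncyclo_young`); (5) mean age inside `age_range`
#' (`age_out_of_range`); (6) an emmetrope-specific AL summary present
#' (`no_emmetrope_al`). The first failing rule sets the reason; ineligibility
#' is a decision, never an error.
#'
#' @param studies Tibble in the [study_csv_columns] schema (means/SDs may
#'   still be unimputed; imputation is applied leniently first).
#' @param criteria A [screening_criteria] object.
#' @return A tibble with columns `study_id`, `eligible`, `reason`
#'   (`reason == "ok"` iff eligible).
#' @export
screen_studies <- function(studies, criteria = screening_criteria()) {
  stopifnot(inherits(criteria, "screening_criteria"))
  df <- impute_summaries(studies, strict = FALSE) |> resolve_age()
  reason <- purrr::map_chr(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (is.na(r$biometry) || r$biometry != "optical") return("ultrasound_al")
    if (is.na(r$ser_lower) || is.na(r$ser_upper) ||
        r$ser_lower < criteria$ser_window[1] ||
        r$ser_upper > criteria$ser_window[2]) return("ser_window_violation")
    if (!r$age_resolved || is.na(r$age_mean)) return("age_imputation_refused")
    cyclo <- isTRUE(r$cycloplegia)
    if (!cyclo && r$age_mean < criteria$noncyclo_min_age) return("noncyclo_young")
    if (r$age_mean < criteria$age_range[1] ||
        r$age_mean > criteria$age_range[2]) return("age_out_of_range")
    if (is.na(r$al_mean)) return("no_emmetrope_al")
    "ok"
  })
  tibble::tibble(study_id = df$study_id, eligible = reason == "ok",
                 reason = reason)
}
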