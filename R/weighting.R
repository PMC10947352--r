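#' Standard error of a reported mean
#'
#' @param sd Sample standard deviation (non-negative).
#' @param n Sample size (positive count).
#' @return `sd / sqrt(n)`.
#' @export
standard_error <- function(sd, n) {
  stopifnot(is.numeric(sd), is.numeric(n))
  if (any(n < 1, na.rm = TRUE) || any(n == 0, na.rm = TRUE)) {
    abort("`n` must be a positive count.")
  }
  if (any(sd < 0, na.rm = TRUE)) abort("`sd` must be non-negative.")
  sd / sqrt(n)
}

#' Min-max normalisation
#'
#' Rescales a vector to the unit interval: `(x - min) / (max - min)`. When all
#' values are equal the range is degenerate and every output is 0, so equally
#' precise studies all receive the maximal weight in [compute_weights].
#'
#' @param x Non-empty numeric vector.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (length(x) == 0) abort("`x` must be non-empty.")
  if (any(!is.finite(x))) abort("`x` must be finite.")
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Precision weights from standard errors of AL and age
#'
#' The study weight
#' \deqn{W_i = \frac{1}{\mathrm{norm}(SE_{AL})_i + \mathrm{norm}(SE_{age})_i + 0.2}}
#' where `norm` is min-max normalisation over the studies entering the fit,
#' so both standard errors contribute on the same 0-1 scale, and the 0.2
#' stabiliser keeps the weight finite when both normalised SEs are zero. The
#' study with both minimal SEs gets exactly 5; every weight lies in
#' `[1/2.2, 5]`. Weights are invariant to rescaling either SE vector by a
#' positive constant.
#'
#' @param se_al Standard errors of the AL means (mm), one per study.
#' @param se_age Standard errors of the age means (years), same length.
#' @return Numeric vector of weights.
#' @export
compute_weights <- function(se_al, se_age) {
  if (length(se_al) != length(se_age)) {
    abort("`se_al` and `se_age` must have the same length.")
  }
  if (length(se_al) == 0) abort("Need at least one study.")
  1 / (minmax_normalize(se_al) + minmax_normalize(se_age) + 0.2)
}

#' Add standard errors and precision weights to a study table
#'
#' Computes `se_al = al_sd / sqrt(n)`, `se_age = age_sd / sqrt(n)` and the
#' [compute_weights] weight over all rows of the table. Normalisation is
#' relative to the supplied table, i.e. the cohort of studies entering the
#' fit, so a refit on a subset re-normalises.
#'
#' @param studies Tibble with completed `al_sd`, `age_sd` and `n` columns
#'   (run [impute_summaries] first if needed).
#' @return The input with `se_al`, `se_age` and `weight` columns appended.
#' @export
add_weights <- function(studies) {
  if (any(is.na(studies$al_sd)) || any(is.na(studies$age_sd))) {
    abort("`al_sd`/`age_sd` contain missing values; impute summaries first.")
  }
  studies |>
    dplyr::mutate(se_al = standard_error(.data$al_sd, .data$n),
                  se_age = standard_error(.data$age_sd, .data$n),
                  weight = compute_weights(.data$se_al, .data$se_age))
}
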