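# Shared fixtures for the test suite. All data are built in code.

# presentation rounding used by the published tables
round_to_2dp <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

# printed parameter triples used as anchors throughout
eq_combined <- function() growth_params(23.60, -5.60, 0.30)
eq_ea <- function() growth_params(23.69, -6.91, 0.33)
eq_nonea <- function() growth_params(23.54, -4.15, 0.24)

# minimal well-formed study tibble (all summaries reported as mean/sd)
make_studies <- function(n_rows = 3) {
  tibble::tibble(
    study_id = paste0("S", seq_len(n_rows)),
    region = "testland",
    group = rep(c("EA", "nonEA"), length.out = n_rows),
    n = c(387, 120, 45)[seq_len(n_rows)],
    age_mean = c(13.2, 7.5, 22.0)[seq_len(n_rows)],
    age_sd = c(0.5, 0.4, 2.1)[seq_len(n_rows)],
    age_median = NA_real_, age_q1 = NA_real_, age_q3 = NA_real_,
    age_min = NA_real_, age_max = NA_real_,
    age_is_whole_sample = FALSE, whole_sample_age_range = NA_real_,
    al_mean = c(23.41, 22.86, 23.62)[seq_len(n_rows)],
    al_sd = c(0.68, 0.61, 0.75)[seq_len(n_rows)],
    al_median = NA_real_, al_q1 = NA_real_, al_q3 = NA_real_,
    al_min = NA_real_, al_max = NA_real_,
    ser_lower = -0.50, ser_upper = 0.50,
    cycloplegia = c(TRUE, TRUE, FALSE)[seq_len(n_rows)],
    biometry = "optical", prop_male = NA_real_
  )
}

# noise-free observations lying exactly on a growth curve, equal weights
noiseless_obs <- function(params = eq_combined(), ages = 6:24) {
  tibble::tibble(
    study_id = paste0("N", seq_along(ages)),
    group = rep(c("EA", "nonEA"), length.out = length(ages)),
    age_mean = as.numeric(ages),
    al_mean = predict_al(params, ages),
    weight = 1
  )
}

# a default synthetic corpus, imputed and weighted, ready to fit
fitted_ready_corpus <- function(seed = 42, ...) {
  cfg <- synthetic_config(seed = seed, ...)
  add_weights(impute_summaries(simulate_corpus(cfg)))
}
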