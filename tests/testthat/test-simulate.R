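test_that("corpora are reproducible from the seed and sized like the source", {
  cfg <- synthetic_config(seed = 11)
  a <- simulate_corpus(cfg)
  b <- simulate_corpus(cfg)
  expect_identical(a, b)
  # default corpus: 16 EA + 12 non-EA study arms
  expect_equal(nrow(a), 28)
  expect_equal(sum(a$group == "EA"), 16)
  expect_equal(sum(a$group == "nonEA"), 12)
  # different seeds give different corpora
  expect_false(identical(a, simulate_corpus(synthetic_config(seed = 12))))
  # every simulated record passes default screening
  expect_true(all(screen_studies(a)$eligible))
})

test_that("empty configuration yields an empty corpus with a warning", {
  cfg <- synthetic_config(n_studies_per_group = c(EA = 0L, nonEA = 0L))
  expect_warning(out <- simulate_corpus(cfg), "Empty corpus")
  expect_equal(nrow(out), 0)
})

test_that("noiseless studies collapse onto the true curve", {
  cfg <- synthetic_config(within_study_age_sd = 0, between_study_sd = 0,
                          individual_al_sd = 0, seed = 5)
  set.seed(5)
  sim <- simulate_study(cfg, "EA", center = 10)
  expect_equal(unique(sim$eyes$age), 10)
  expect_equal(sim$record$al_mean,
               predict_al(cfg$true_params$EA, 10))
  expect_equal(sim$record$al_sd, 0)
})

test_that("records summarise their own eyes exactly", {
  cfg <- synthetic_config(seed = 3)
  set.seed(3)
  sim <- simulate_study(cfg, "nonEA", "x")
  expect_equal(sim$record$al_mean, mean(sim$eyes$al))
  expect_equal(sim$record$al_sd, sd(sim$eyes$al))
  expect_equal(sim$record$age_mean, mean(sim$eyes$age))
  expect_equal(sim$record$n, nrow(sim$eyes))

  # median/IQR style omits means and sds
  cfg2 <- synthetic_config(reporting_style = "median_iqr", seed = 3)
  set.seed(3)
  sim2 <- simulate_study(cfg2, "nonEA", "x")
  expect_true(is.na(sim2$record$al_mean))
  expect_equal(sim2$record$al_median, median(sim2$eyes$al))

  cfg3 <- synthetic_config(reporting_style = "median_range", seed = 3)
  set.seed(3)
  sim3 <- simulate_study(cfg3, "nonEA", "x")
  expect_equal(sim3$record$al_min, min(sim3$eyes$al))
  expect_equal(sim3$record$al_max, max(sim3$eyes$al))
})

test_that("study-mean variance decomposes into its two components", {
  # sd of study means at a fixed age centre is close to
  # sqrt(between^2 + individual^2 / n)
  cfg <- synthetic_config(between_study_sd = 0.2, individual_al_sd = 0.6,
                          within_study_age_sd = 0, seed = 10)
  set.seed(10)
  n <- 100
  means <- replicate(1000, {
    u <- rnorm(1, 0, cfg$between_study_sd)
    mean(predict_al(cfg$true_params$EA, 12) + u +
           rnorm(n, 0, cfg$individual_al_sd))
  })
  expect_lt(abs(sd(means) - sqrt(0.2^2 + 0.6^2 / n)) / sqrt(0.2^2 + 0.6^2 / n),
            0.10)
})

test_that("median-reported corpora still recover the curve via imputation", {
  # identical underlying truth reported as mean/sd vs median/IQR should give
  # near-identical fitted asymptotes after imputation
  truth <- list(EA = eq_combined(), nonEA = eq_combined())
  base <- synthetic_config(true_params = truth,
                           n_studies_per_group = c(EA = 100L, nonEA = 100L),
                           seed = 60)
  iqr_cfg <- synthetic_config(true_params = truth,
                              n_studies_per_group = c(EA = 100L, nonEA = 100L),
                              reporting_style = "median_iqr", seed = 60)
  fit_a <- fit_combined(add_weights(impute_summaries(simulate_corpus(base))),
                        seed = 2)
  fit_b <- fit_combined(add_weights(impute_summaries(simulate_corpus(iqr_cfg))),
                        seed = 2)
  expect_lt(abs(fit_a$parameters[["a"]] - fit_b$parameters[["a"]]), 0.1)
  expect_lt(abs(fit_b$parameters[["a"]] - 23.60), 0.1)
})

test_that("yaml configs round-trip into synthetic_config", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_studies_per_group:", "  EA: 4", "  nonEA: 5",
    "seed: 99", "reporting_style: median_range",
    "true_params:",
    "  EA: {a: 23.7, b: -6.9, c: 0.33}",
    "  nonEA: {a: 23.5, b: -4.2, c: 0.24}"), path)
  cfg <- synthetic_config_from_yaml(path)
  expect_equal(cfg$n_studies_per_group, c(EA = 4, nonEA = 5))
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$true_params$EA$a, 23.7)
  expect_equal(cfg$reporting_style, "median_range")
})
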