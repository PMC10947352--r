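test_that("noise-free curves are recovered essentially exactly", {
  obs <- noiseless_obs(eq_combined())
  fit <- fit_combined(obs, seed = 1)
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters), c(23.60, -5.60, 0.30), tolerance = 1e-4)
  # weighted NLS route as well
  fit2 <- fit_combined(obs, random_effects = FALSE, seed = 1)
  expect_equal(unname(fit2$parameters), c(23.60, -5.60, 0.30), tolerance = 1e-6)
})

test_that("the marginal likelihood has the documented invariances", {
  obs <- fitted_ready_corpus(seed = 7)
  theta <- c(a = 23.6, b = -5.6, c = 0.3)
  base <- negative_log_marginal_likelihood(theta, sigma2 = 0.02, tau2 = 0.03, obs)
  expect_true(is.finite(base))
  # scale confounding: weights and sigma2 are only identified through the
  # ratio sigma2 / W, so scaling both by the same factor changes nothing
  obs2 <- dplyr::mutate(obs, weight = weight * 2)
  expect_equal(negative_log_marginal_likelihood(theta, 0.04, 0.03, obs2), base)
  # grouped parametrisation with zero deltas equals the combined value
  theta_g <- c(a_nonEA = 23.6, b_nonEA = -5.6, c_nonEA = 0.3,
               delta_a = 0, delta_b = 0, delta_c = 0)
  expect_equal(negative_log_marginal_likelihood(theta_g, 0.02, 0.03, obs,
                                                grouped = TRUE), base)
  expect_error(negative_log_marginal_likelihood(theta, -1, 0.03, obs), "sigma2")
})

test_that("a single study pins the curve through its own observation", {
  # with one perfectly weighted study, the likelihood in the mean parameters
  # is maximised exactly where the curve passes through the observation
  obs <- tibble::tibble(age_mean = 10, al_mean = 23.0, weight = 1)
  through <- c(a = 23.5, b = (23.0 - 23.5) / exp(-0.3 * 10), c = 0.3)
  away <- c(a = 23.5, b = through[["b"]] + 0.5, c = 0.3)
  expect_lt(negative_log_marginal_likelihood(through, 0.01, 0.01, obs),
            negative_log_marginal_likelihood(away, 0.01, 0.01, obs))
})

test_that("with tau2 = 0 the optimiser matches independent weighted NLS", {
  skip_if_not_installed("minpack.lm")
  # low-noise fixture corpus so the least-squares problem has an interior
  # optimum and the unbounded reference solver and the bounded one target the
  # same stationary point
  obs <- fitted_ready_corpus(seed = 42, between_study_sd = 0.05)
  fit <- fit_combined(obs, random_effects = FALSE, seed = 5)
  oracle <- minpack.lm::nlsLM(
    al_mean ~ a + b * exp(-c * age_mean),
    data = obs, weights = obs$weight,
    start = list(a = 24, b = -6, c = 0.4),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  expect_equal(unname(fit$parameters), unname(coef(oracle)),
               tolerance = 1e-6)
})

test_that("grouped fits honour the reference-offset structure", {
  obs <- fitted_ready_corpus(seed = 13)
  fit <- fit_grouped(obs, seed = 4)
  expect_true(fit$converged)
  p <- fit$parameters
  ea <- params_for_group(fit, "EA")
  expect_equal(ea$a, p[["a_nonEA"]] + p[["delta_a"]])
  expect_equal(ea$b, p[["b_nonEA"]] + p[["delta_b"]])
  expect_equal(ea$c, p[["c_nonEA"]] + p[["delta_c"]])

  # relabelling the reference negates the deltas and leaves curves unchanged
  flipped <- fit_grouped(obs, reference = "EA", seed = 4)
  expect_equal(flipped$parameters[["delta_a"]], -p[["delta_a"]], tolerance = 1e-3)
  expect_equal(flipped$parameters[["delta_c"]], -p[["delta_c"]], tolerance = 1e-3)
  for (g in c("EA", "nonEA")) {
    expect_equal(predict_al(params_for_group(flipped, g), 6:24),
                 predict_al(params_for_group(fit, g), 6:24), tolerance = 1e-3)
  }

  # freezing the deltas at zero reproduces the combined fit
  null_fit <- fit_grouped(obs, fix_deltas = TRUE, seed = 4)
  comb <- fit_combined(obs, seed = 4)
  expect_equal(unname(null_fit$parameters), unname(comb$parameters),
               tolerance = 1e-6)

  expect_error(fit_grouped(dplyr::filter(obs, group == "EA"), seed = 1),
               "absent")
})

test_that("the returned optimum beats every multi-start candidate", {
  obs <- fitted_ready_corpus(seed = 55)
  fit <- fit_combined(obs, seed = 9)
  expect_true(all(-fit$loglik <= fit$trace$objective + 1e-8))
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$loglik)
  # deterministic given the seed
  fit2 <- fit_combined(obs, seed = 9)
  expect_identical(fit$parameters, fit2$parameters)
})

test_that("grouping lowers AIC when the groups genuinely differ", {
  cfg <- synthetic_config(
    true_params = list(EA = growth_params(23.69, -6.91, 0.33),
                       nonEA = growth_params(23.54, -4.15, 0.24)),
    n_studies_per_group = c(EA = 40L, nonEA = 40L), seed = 321)
  obs <- add_weights(impute_summaries(simulate_corpus(cfg)))
  comb <- fit_combined(obs, seed = 2)
  grp <- fit_grouped(obs, seed = 2)
  expect_lte(grp$aic, comb$aic + 1e-6)
})

test_that("degenerate designs are refused", {
  obs <- tibble::tibble(age_mean = rep(10, 5), al_mean = rnorm(5, 23, 0.1),
                        weight = 1)
  expect_error(fit_combined(obs, seed = 1), "distinct mean ages")
  expect_error(fit_combined(noiseless_obs(ages = c(6, 12)), seed = 1),
               "distinct mean ages")
})

test_that("tidy and glance expose broom-style summaries", {
  obs <- fitted_ready_corpus(seed = 77)
  fit <- fit_grouped(obs, seed = 3)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value",
                     "conf.low", "conf.high"))
  expect_equal(td$term, names(fit$parameters))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(gl$nobs, 28)
  expect_true(gl$grouped)
})

test_that("Wald coverage approaches nominal as the corpus grows", {
  # at 60 studies per group the likelihood is near-quadratic and the
  # Hessian-based intervals should be close to their nominal level; this
  # guards against gross SE miscalibration without asserting the small-corpus
  # behaviour, which is documented separately
  truth <- eq_combined()
  cover <- t(vapply(1:40, function(i) {
    cfg <- synthetic_config(true_params = list(EA = truth, nonEA = truth),
                            n_studies_per_group = c(EA = 60L, nonEA = 60L),
                            seed = 5000 + i)
    obs <- add_weights(impute_summaries(simulate_corpus(cfg)))
    td <- tidy(fit_combined(obs, seed = i))
    td$conf.low <= c(23.60, -5.60, 0.30) & td$conf.high >= c(23.60, -5.60, 0.30)
  }, logical(3)))
  expect_gte(mean(cover[, 1]), 0.85)  # a
  expect_gte(mean(cover[, 2]), 0.80)  # b
  expect_gte(mean(cover[, 3]), 0.85)  # c
})
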