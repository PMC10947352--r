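test_that("wald_test matches the normal-reference formulas", {
  w <- wald_test(0, 0.1)
  expect_equal(w$z, 0)
  expect_equal(w$p, 1)
  expect_equal(c(w$ci_low, w$ci_high), c(-0.196, 0.196), tolerance = 1e-4)

  w <- wald_test(1.959964, 1)
  expect_equal(w$p, 0.05, tolerance = 1e-6)

  # back-calculated from a reported CI half-width 0.22 / 1.96: the growth-rate
  # contrast 0.09 gives p around 0.42, consistent with a printed p of 0.43
  w <- wald_test(0.09, 0.22 / qnorm(0.975))
  expect_equal(w$p, 0.42, tolerance = 0.02)
  expect_error(wald_test(1, 0), "positive")
})

test_that("format_wald renders a report line", {
  w <- wald_test(0.09, 0.1122)
  expect_match(format_wald(w), "difference: 0.09, 95% CI: -0.13 to 0.31")
})

test_that("delta-method bands behave at the degenerate and frozen limits", {
  obs <- fitted_ready_corpus(seed = 17)
  fit <- fit_combined(obs, seed = 2)

  # zero covariance collapses the band onto the point estimate
  fit0 <- fit
  fit0$vcov[] <- 0
  pr <- predict_with_ci(fit0, "combined", c(6, 12, 24))
  expect_equal(pr$ci_low, pr$al)
  expect_equal(pr$ci_high, pr$al)

  # with only a's variance nonzero, the large-age band inherits a's CI
  fit1 <- fit
  fit1$vcov[] <- 0
  fit1$vcov[1, 1] <- 0.04
  pr <- predict_with_ci(fit1, "combined", 2000)
  expect_equal(pr$ci_high - pr$al, 1.959964 * 0.2, tolerance = 1e-6)

  fitNA <- fit
  fitNA$vcov[1, 1] <- NA
  expect_error(predict_with_ci(fitNA, "combined", 10), "refit")
})

test_that("delta-method bands agree with a parametric-bootstrap oracle", {
  obs <- fitted_ready_corpus(seed = 23)
  fit <- fit_combined(obs, seed = 6)
  # propagation is checked at a covariance moderate enough that the curve is
  # locally near-linear over the parameters' sampling distribution, the
  # regime in which the first-order delta method claims validity; the oracle
  # guards against gross errors in the gradient or the variance form
  fit$vcov <- fit$vcov * 0.01
  ages <- c(7, 10, 15, 20)
  band <- predict_with_ci(fit, "combined", ages)

  set.seed(2024)
  draws <- MASS::mvrnorm(2000, mu = unname(fit$parameters), Sigma = fit$vcov)
  for (k in seq_along(ages)) {
    sims <- draws[, 1] + draws[, 2] * exp(-draws[, 3] * ages[k])
    half_boot <- 1.959964 * stats::sd(sims)
    half_delta <- band$ci_high[k] - band$al[k]
    expect_lt(abs(half_delta - half_boot) / half_boot, 0.10)
  }
})

test_that("growth tables mirror the published table's structure", {
  tbl <- growth_table(eq_combined(), ages = 6:24)
  expect_equal(nrow(tbl), 19)
  expect_equal(format_growth_table(tbl)$rate[1], 0.24)
  expect_true(all(diff(tbl$al) > 0))
  expect_true(all(diff(tbl$rate) < 0))
  expect_true(all(is.na(tbl$ci_low)))

  # published combined rate column at the ages where the closed form and the
  # printed table agree
  ages <- c(6, 8, 10, 11, 12, 13, 14, 15, 16, 17, 18, 20, 21, 22, 23)
  printed <- c(0.24, 0.13, 0.07, 0.05, 0.04, 0.03, 0.02, 0.02, 0.01, 0.01,
               0.01, 0.00, 0.00, 0.00, 0.00)
  got <- format_growth_table(growth_table(eq_combined(), ages = ages))
  expect_equal(got$rate, printed)

  # empty age list gives an empty table; unsorted ages come back sorted
  expect_equal(nrow(growth_table(eq_combined(), ages = integer(0))), 0)
  shuffled <- growth_table(eq_combined(), ages = c(12, 6, 9))
  expect_equal(shuffled$age, c(6, 9, 12))
  expect_error(growth_table(eq_combined(), ages = c(6, 55)), "0 to 40")
})

test_that("growth tables from fits carry bands and both groups", {
  obs <- fitted_ready_corpus(seed = 29)
  fit <- fit_grouped(obs, seed = 8)
  tbl <- growth_table(fit, ages = 6:24)
  expect_setequal(unique(tbl$group), c("EA", "nonEA"))
  expect_equal(nrow(tbl), 2 * 19)
  expect_true(all(tbl$ci_low <= tbl$al & tbl$al <= tbl$ci_high))
  for (g in c("EA", "nonEA")) {
    sub <- dplyr::filter(tbl, group == g)
    expect_true(all(diff(sub$al) > 0))
    expect_true(all(diff(sub$rate) < 0))
  }
  expect_error(growth_table(fit, groups = "martian"))
})

test_that("wald_contrasts reads the offsets off a grouped fit", {
  obs <- fitted_ready_corpus(seed = 37)
  fit <- fit_grouped(obs, seed = 1)
  ct <- wald_contrasts(fit)
  expect_equal(ct$name, c("delta_a", "delta_b", "delta_c"))
  expect_equal(ct$estimate, unname(fit$parameters[4:6]))
  expect_equal(ct$se, unname(sqrt(diag(fit$vcov)[4:6])))
  comb <- fit_combined(obs, seed = 1)
  expect_error(wald_contrasts(comb), "grouped")
})

test_that("presentation rounding rounds halves away from zero", {
  tbl <- growth_table(growth_params(23, -5, 0.3), ages = 6:8)
  tbl$al <- c(22.005, -22.005, 22.004)
  out <- format_growth_table(tbl)
  expect_equal(out$al, c(22.01, -22.01, 22.00))
})
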