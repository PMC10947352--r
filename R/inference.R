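#' Wald test of a single estimate
#'
#' `z = estimate / se`, two-sided p-value `2 * (1 - pnorm(|z|))`, and a 95%
#' interval `estimate +/- 1.959964 * se`.
#'
#' @param estimate Point estimate.
#' @param se Standard error (strictly positive).
#' @param name Optional parameter label.
#' @return A one-row tibble: `name`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `z`, `p`.
#' @examples
#' wald_test(0.09, 0.1122)
#' @export
wald_test <- function(estimate, se, name = NA_character_) {
  stopifnot(is.numeric(estimate), is.numeric(se))
  if (any(se <= 0) || any(!is.finite(se))) abort("`se` must be positive and finite.")
  z <- estimate / se
  tibble::tibble(name = name, estimate = estimate, se = se,
                 ci_low = estimate - Z975 * se, ci_high = estimate + Z975 * se,
                 z = z, p = 2 * (1 - pnorm(abs(z))))
}

#' Wald tests on the ethnic-group parameter contrasts
#'
#' For a grouped fit, tests each between-group offset (`delta_a`, `delta_b`,
#' `delta_c`) against zero using the standard errors read directly from the
#' fit's covariance in the reference-plus-offset parametrisation. The three
#' p-values are reported raw (no multiplicity correction).
#'
#' @param fit A grouped `al_growth_fit`.
#' @return A tibble with one [wald_test] row per contrast.
#' @export
wald_contrasts <- function(fit) {
  stopifnot(inherits(fit, "al_growth_fit"))
  if (!fit$grouped || fit$fix_deltas) {
    abort("Contrasts require a grouped fit with free delta parameters.")
  }
  idx <- grep("^delta_", names(fit$parameters))
  se <- sqrt(diag(fit$vcov))[idx]
  wald_test(unname(fit$parameters[idx]), unname(se),
            name = names(fit$parameters)[idx])
}

#' Format a Wald result as a report line
#'
#' @param w A one-or-more-row tibble from [wald_test].
#' @param digits Digits for estimates and CI bounds.
#' @return Character vector like
#'   `"difference: 0.09, 95% CI: -0.13 to 0.31, p = 0.43"`.
#' @export
format_wald <- function(w, digits = 2) {
  num <- function(x, d = digits) formatC(round_half_up(x, d), format = "f",
                                         digits = d)
  sprintf("difference: %s, 95%% CI: %s to %s, p = %s",
          num(w$estimate), num(w$ci_low), num(w$ci_high), num(w$p, 2))
}

# gradient of the predicted AL w.r.t. the fit's parameter vector
prediction_gradient <- function(fit, group, age) {
  p <- fit$parameters
  if (!fit$grouped || fit$fix_deltas) {
    E <- exp(-p[[3]] * age)
    g <- cbind(1, E, -p[[2]] * age * E)
  } else {
    alt <- group != fit$reference
    gp <- params_for_group(fit, group)
    E <- exp(-gp$c * age)
    base <- cbind(1, E, -gp$b * age * E)
    g <- cbind(base, if (alt) base else base * 0)
  }
  g
}

#' Predicted AL with a delta-method confidence band
#'
#' Point prediction from the group's fitted curve, with variance
#' `g' Sigma g` where `g` is the gradient of the growth curve in the fit's
#' parametrisation (for the non-reference group, the chain rule through
#' reference + offset makes the gradient repeat across both blocks) and
#' `Sigma` the estimated parameter covariance. The 95% band is
#' `+/- 1.959964` standard deviations.
#'
#' @param fit An `al_growth_fit`.
#' @param group `"combined"` for an ungrouped fit; `"EA"` or `"nonEA"` for a
#'   grouped fit.
#' @param age Numeric vector of ages (years).
#' @return A tibble: `age`, `group`, `al`, `se`, `ci_low`, `ci_high`.
#' @export
predict_with_ci <- function(fit, group, age) {
  stopifnot(inherits(fit, "al_growth_fit"))
  if (!fit$converged) warn("Fit did not converge; predictions may be unreliable.")
  if (any(!is.finite(fit$vcov))) {
    abort("Parameter covariance is singular or unavailable; refit the model.")
  }
  params <- params_for_group(fit, group)
  al <- predict_al(params, age)
  G <- prediction_gradient(fit, group, age)
  v <- rowSums((G %*% fit$vcov) * G)
  if (any(v < -1e-10)) abort("Covariance is not positive semidefinite; refit the model.")
  se <- sqrt(pmax(v, 0))
  tibble::tibble(age = age, group = group, al = al, se = se,
                 ci_low = al - Z975 * se, ci_high = al + Z975 * se)
}

#' Age-specific growth table
#'
#' One row per age and group with the predicted AL, its 95% delta-method
#' confidence band, and the forward-difference annual growth rate — the shape
#' of an AL growth-chart table. Values are kept at full precision; use
#' [format_growth_table] for a 2-dp presentation copy.
#'
#' @param object An `al_growth_fit`, or a [growth_params] object (in which
#'   case the CI columns are `NA` unless `covariance` is supplied as the 3x3
#'   parameter covariance).
#' @param ages Integer ages in years, within 0 to 40 (default `6:24`). Rows
#'   are emitted sorted ascending.
#' @param groups Groups to tabulate; defaults to both groups of a grouped
#'   fit, `"combined"` otherwise.
#' @param covariance Optional covariance matrix when `object` is a bare
#'   parameter triple.
#' @return A `growth_table` tibble: `age`, `group`, `al`, `ci_low`,
#'   `ci_high`, `rate`.
#' @export
growth_table <- function(object, ages = 6:24, groups = NULL, covariance = NULL) {
  if (any(ages < 0 | ages > 40)) abort("`ages` must lie within 0 to 40 years.")
  ages <- sort(unique(ages))
  if (inherits(object, "growth_params")) {
    groups <- groups %||% "combined"
    rows <- purrr::map(groups, function(g) {
      al <- predict_al(object, ages)
      if (is.null(covariance)) {
        se <- rep(NA_real_, length(ages))
      } else {
        E <- exp(-object$c * ages)
        G <- cbind(1, E, -object$b * ages * E)
        se <- sqrt(pmax(rowSums((G %*% covariance) * G), 0))
      }
      tibble::tibble(age = ages, group = g, al = al,
                     ci_low = al - Z975 * se, ci_high = al + Z975 * se,
                     rate = annual_growth_rate(object, ages))
    })
  } else if (inherits(object, "al_growth_fit")) {
    groups <- groups %||% if (object$grouped && !object$fix_deltas) {
      c("EA", "nonEA")
    } else "combined"
    rows <- purrr::map(groups, function(g) {
      pr <- predict_with_ci(object, g, ages)
      pr$rate <- annual_growth_rate(params_for_group(object, g), ages)
      pr[, c("age", "group", "al", "ci_low", "ci_high", "rate")]
    })
  } else {
    abort("`object` must be an al_growth_fit or growth_params object.")
  }
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$group, .data$age)
  class(out) <- c("growth_table", class(out))
  out
}

#' Round a growth table for presentation
#'
#' Rounds AL, CI and rate columns to `digits` decimal places with halves
#' rounded away from zero, mirroring printed growth-chart tables. The
#' full-precision table should be used for any further computation.
#'
#' @param table A [growth_table] tibble.
#' @param digits Decimal places (default 2).
#' @return A tibble of the same shape with rounded numeric columns.
#' @export
format_growth_table <- function(table, digits = 2) {
  dplyr::mutate(table, dplyr::across(c("al", "ci_low", "ci_high", "rate"),
                                     ~ round_half_up(.x, digits)))
}
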