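# Internal observation container: x = mean age, y = mean AL, w = weight,
# alt = indicator of the non-reference ethnic group (NULL for combined fits).
make_obs <- function(data, grouped, reference) {
  need <- c("age_mean", "al_mean", "weight")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Data lack column(s): %s (run impute_summaries() and add_weights()).",
                  paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(data$weight)) || any(data$weight <= 0)) {
    abort("Weights must be positive and finite.")
  }
  alt <- NULL
  if (grouped) {
    levels <- c("EA", "nonEA")
    if (!reference %in% levels) abort("`reference` must be 'EA' or 'nonEA'.")
    bad <- setdiff(unique(data$group), levels)
    if (length(bad) > 0) abort(sprintf("Unknown group label '%s'.", bad[1]))
    for (g in levels) {
      if (!g %in% data$group) abort(sprintf("Group '%s' is absent from the data.", g))
    }
    alt <- data$group != reference
  }
  list(x = data$age_mean, y = data$al_mean, w = data$weight, alt = alt,
       n = nrow(data))
}

# mean curve and its Jacobian in the fitting parametrisation
# combined: theta = (a, b, c); grouped: theta = (a_ref, b_ref, c_ref, da, db, dc)
mean_curve <- function(theta, obs) {
  if (is.null(obs$alt)) {
    theta[1] + theta[2] * exp(-theta[3] * obs$x)
  } else {
    i <- as.numeric(obs$alt)
    (theta[1] + i * theta[4]) +
      (theta[2] + i * theta[5]) * exp(-(theta[3] + i * theta[6]) * obs$x)
  }
}

#' Negative log marginal likelihood of the weighted mixed-effects model
#'
#' With one summary observation per study and a study-level random intercept
#' on the asymptote, the marginal variance of study \eqn{i} is
#' \eqn{v_i = \tau^2 + \sigma^2 / W_i}, where \eqn{\tau^2} is the
#' between-study variance, \eqn{\sigma^2} the residual scale and \eqn{W_i} the
#' precision weight. Returns
#' \eqn{-\sum_i \log N(y_i; f(x_i; \theta_{g(i)}), v_i)}.
#'
#' @param params Named numeric vector of mean parameters: `a`, `b`, `c` for a
#'   combined model; `a_<ref>`, `b_<ref>`, `c_<ref>`, `delta_a`, `delta_b`,
#'   `delta_c` for a grouped model.
#' @param sigma2,tau2 Residual variance scale and between-study variance
#'   (both positive; `tau2` may be 0).
#' @param data Tibble with `age_mean`, `al_mean`, `weight` and, for grouped
#'   models, `group`.
#' @param grouped Whether `params` follow the grouped parametrisation.
#' @param reference Reference group label for grouped models.
#' @return The negative log likelihood (a finite scalar for finite inputs).
#' @export
negative_log_marginal_likelihood <- function(params, sigma2, tau2, data,
                                             grouped = FALSE,
                                             reference = "nonEA") {
  if (sigma2 <= 0) abort("`sigma2` must be positive.")
  if (tau2 < 0) abort("`tau2` must be non-negative.")
  obs <- make_obs(data, grouped, reference)
  v <- tau2 + sigma2 / obs$w
  r <- obs$y - mean_curve(unname(params), obs)
  0.5 * sum(log(2 * pi * v) + r^2 / v)
}

# --- optimisation parametrisation ------------------------------------------
# Each curve is optimised as phi = (asymptote a, age-0 intercept i0 = a + b,
# rate c) so that biological plausibility bounds are simple boxes; the
# reporting parametrisation theta = (a, b, c) (and, grouped, reference +
# delta) is a fixed linear map M of phi, so vcov_theta = M vcov_phi M'.
# Combined: phi = (a, i0, c); grouped: phi = (a_ref, i0_ref, c_ref,
# a_alt, i0_alt, c_alt).

phi_curve <- function(phi, obs) {
  if (is.null(obs$alt)) {
    E <- exp(-phi[3] * obs$x)
    phi[1] * (1 - E) + phi[2] * E
  } else {
    i <- as.numeric(obs$alt)
    a <- phi[1] + i * (phi[4] - phi[1])
    i0 <- phi[2] + i * (phi[5] - phi[2])
    cc <- phi[3] + i * (phi[6] - phi[3])
    E <- exp(-cc * obs$x)
    a * (1 - E) + i0 * E
  }
}

phi_jacobian <- function(phi, obs) {
  x <- obs$x
  if (is.null(obs$alt)) {
    E <- exp(-phi[3] * x)
    cbind(1 - E, E, -(phi[2] - phi[1]) * x * E)
  } else {
    i <- as.numeric(obs$alt)
    a <- phi[1] + i * (phi[4] - phi[1])
    i0 <- phi[2] + i * (phi[5] - phi[2])
    cc <- phi[3] + i * (phi[6] - phi[3])
    E <- exp(-cc * x)
    dc <- -(i0 - a) * x * E
    cbind((1 - E) * (1 - i), E * (1 - i), dc * (1 - i),
          (1 - E) * i, E * i, dc * i)
  }
}

# linear map from phi to the reporting parametrisation
phi_report_matrix <- function(p) {
  if (p == 3) {
    matrix(c(1, 0, 0,
             -1, 1, 0,
             0, 0, 1), 3, 3, byrow = TRUE)
  } else {
    matrix(c(1, 0, 0, 0, 0, 0,    # a_ref
             -1, 1, 0, 0, 0, 0,   # b_ref = i0_ref - a_ref
             0, 0, 1, 0, 0, 0,    # c_ref
             -1, 0, 0, 1, 0, 0,   # delta_a = a_alt - a_ref
             1, -1, 0, -1, 1, 0,  # delta_b = b_alt - b_ref
             0, 0, -1, 0, 0, 1),  # delta_c = c_alt - c_ref
           6, 6, byrow = TRUE)
  }
}

phi_nll <- function(phi, lsig, ltau, obs) {
  sigma2 <- exp(lsig); tau2 <- exp(ltau)
  v <- tau2 + sigma2 / obs$w
  r <- obs$y - phi_curve(phi, obs)
  0.5 * sum(log(2 * pi * v) + r^2 / v)
}

phi_nll_grad <- function(phi, lsig, ltau, obs) {
  sigma2 <- exp(lsig); tau2 <- exp(ltau)
  v <- tau2 + sigma2 / obs$w
  r <- obs$y - phi_curve(phi, obs)
  J <- phi_jacobian(phi, obs)
  g_mean <- -as.vector(crossprod(J, r / v))
  dv <- 0.5 / v - r^2 / (2 * v^2)
  c(g_mean, sum(dv * sigma2 / obs$w), sum(dv * tau2))
}

# profiled objective with tau2 = 0: sigma2 drops out, leaving weighted NLS
wnls_objective <- function(phi, obs) {
  r <- obs$y - phi_curve(phi, obs)
  0.5 * obs$n * log(sum(obs$w * r^2))
}

wnls_gradient <- function(phi, obs) {
  r <- obs$y - phi_curve(phi, obs)
  J <- phi_jacobian(phi, obs)
  -obs$n * as.vector(crossprod(J, obs$w * r)) / sum(obs$w * r^2)
}

# damped Gauss-Newton refinement of a weighted nonlinear least-squares
# optimum (quadratic convergence near the solution); steps are clamped to the
# feasible box, and unclamped steps leave an interior optimum untouched
wnls_polish <- function(phi, obs, lower, upper, max_iter = 100, tol = 1e-13) {
  S <- function(ph) sum(obs$w * (obs$y - phi_curve(ph, obs))^2)
  s_old <- S(phi)
  for (iter in seq_len(max_iter)) {
    r <- obs$y - phi_curve(phi, obs)
    J <- phi_jacobian(phi, obs)
    JtW <- t(J * obs$w)
    step <- tryCatch(solve(JtW %*% J, JtW %*% r), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    repeat {
      cand <- pmin(pmax(phi + lambda * as.vector(step), lower), upper)
      s_new <- S(cand)
      if (is.finite(s_new) && s_new <= s_old) break
      lambda <- lambda / 2
      if (lambda < 1e-10) { cand <- phi; s_new <- s_old; break }
    }
    moved <- max(abs(cand - phi) / pmax(abs(phi), 1))
    phi <- cand
    if (s_old - s_new < tol * (abs(s_new) + tol) && moved < 1e-12) break
    s_old <- s_new
  }
  phi
}
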