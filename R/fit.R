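#' Fit the weighted nonlinear mixed-effects growth curve
#'
#' Fits the asymptotic growth model `AL = a + b * exp(-c * age)` to
#' study-level means by maximum likelihood, with each study's marginal
#' variance `v_i = tau2 + sigma2 / W_i` (a study-level random intercept on
#' the asymptote plus a precision-weight residual variance function). With
#' `grouped = TRUE` the mean is parametrised as a reference-level triple plus
#' East-Asian-minus-reference offsets (`delta_a`, `delta_b`, `delta_c`), so
#' Wald tests on ethnic differences read directly off the fit's covariance.
#'
#' Optimisation is multi-start quasi-Newton (`L-BFGS-B` with analytic
#' gradients) on `(mean parameters, log sigma2, log tau2)`, started from a
#' grid around the heuristics `a0 = max(AL) + 0.1`, `b0 = min(AL) - a0`,
#' `c0 in {0.1, 0.3, 0.6}`, with remaining starts jittered deterministically
#' from `seed`. With `random_effects = FALSE`, `tau2` is fixed at 0 and
#' `sigma2` profiled out, which reduces the problem to weighted nonlinear
#' least squares; the optimum is then refined by damped Gauss-Newton.
#'
#' @param data Tibble of eligible studies with `age_mean`, `al_mean`,
#'   `weight` (and `group` when `grouped = TRUE`). If `weight` is absent but
#'   `al_sd`/`age_sd`/`n` are present, [add_weights] is applied first.
#' @param grouped Fit the two-level ethnicity parametrisation?
#' @param random_effects If `FALSE`, the between-study variance `tau2` is
#'   fixed at 0 (pure weighted nonlinear least squares).
#' @param starts Number of multi-start initialisations (default 8).
#' @param seed Integer seed controlling the jittered starts; recorded in the
#'   result. The caller's RNG state is preserved.
#' @param reference Reference group for grouped fits (default `"nonEA"`).
#' @param fix_deltas For grouped fits, freeze all three offsets at 0 (the
#'   nested null model; its estimates coincide with the combined fit).
#' @param bounds Plausibility box for each fitted curve, a list with elements
#'   `a` (final AL, mm), `intercept` (age-0 AL `a + b`, mm) and `c` (rate,
#'   per year); see [growth_bounds]. The asymptotic model is only weakly
#'   identified in `(b, c)` when a corpus carries little information about
#'   the bend of the curve, and its likelihood can then increase without
#'   limit along a ridge of biologically impossible curves; constraining the
#'   optimiser to the plausible domain keeps the estimator defined. Interior
#'   optima are unaffected.
#' @param tol Convergence tolerance on the objective (default 1e-9).
#' @return An object of class `al_growth_fit`: a list with `parameters`
#'   (named mean-parameter estimates), `vcov` (their covariance from the
#'   inverted numerical Hessian), `sigma2`, `tau2`, `tau2_boundary`,
#'   `loglik`, `aic`, `converged`, `n_studies`, `trace` (one row per start)
#'   and bookkeeping fields (`grouped`, `reference`, `seed`, `method`).
#' @seealso [fit_combined], [fit_grouped], [wald_contrasts], [growth_table]
#' @export
fit_al_growth <- function(data, grouped = FALSE, random_effects = TRUE,
                          starts = 8, seed = 1L, reference = "nonEA",
                          fix_deltas = FALSE, bounds = growth_bounds(),
                          tol = 1e-9) {
  if (!"weight" %in% names(data)) data <- add_weights(data)
  use_grouped <- grouped && !fix_deltas
  obs <- make_obs(data, use_grouped, reference)
  if (length(unique(obs$x)) < 3) {
    abort("Degenerate design: need at least 3 distinct mean ages.")
  }
  if (obs$n < 3) abort("Need at least 3 studies.")
  p <- if (use_grouped) 6L else 3L
  pnames <- if (use_grouped) {
    c(paste0(c("a_", "b_", "c_"), reference), c("delta_a", "delta_b", "delta_c"))
  } else if (grouped) {
    paste0(c("a_", "b_", "c_"), reference)
  } else c("a", "b", "c")

  box <- phi_box(bounds, p)
  start_list <- with_preserved_seed(seed, build_starts(obs, p, starts, box))

  if (random_effects) {
    fit <- fit_ml(obs, start_list, p, tol, box)
  } else {
    fit <- fit_wnls(obs, start_list, p, tol, box)
  }

  M <- phi_report_matrix(p)
  theta <- setNames(as.vector(M %*% fit$phi), pnames)
  vc <- M %*% fit$vcov %*% t(M)
  dimnames(vc) <- list(pnames, pnames)
  k <- p + if (random_effects) 2L else 1L
  structure(list(
    parameters = theta,
    vcov = vc,
    sigma2 = fit$sigma2,
    tau2 = fit$tau2,
    tau2_boundary = fit$tau2_boundary,
    loglik = fit$loglik,
    aic = 2 * k - 2 * fit$loglik,
    k = k,
    converged = fit$converged,
    n_studies = obs$n,
    grouped = grouped,
    reference = if (grouped) reference else NA_character_,
    fix_deltas = fix_deltas,
    random_effects = random_effects,
    method = "ML",
    seed = seed,
    trace = fit$trace,
    data = tibble::tibble(age_mean = obs$x, al_mean = obs$y, weight = obs$w,
                          group = if (use_grouped) {
                            ifelse(obs$alt, setdiff(c("EA", "nonEA"), reference),
                                   reference)
                          } else if ("group" %in% names(data)) data$group
                            else "combined")
  ), class = "al_growth_fit")
}

#' @rdname fit_al_growth
#' @param ... Passed on to [fit_al_growth].
#' @export
fit_combined <- function(data, ...) fit_al_growth(data, grouped = FALSE, ...)

#' @rdname fit_al_growth
#' @export
fit_grouped <- function(data, ...) fit_al_growth(data, grouped = TRUE, ...)

#' Plausibility bounds for the fitted growth curve
#'
#' The optimiser constrains every fitted curve (each group's curve in a
#' grouped fit) to a biologically plausible box: the final AL `a` within the
#' same 18-28 mm window used to validate study AL summaries at read time; the
#' age-0 intercept `a + b` within a liberal window around the newborn eye
#' (about 17 mm at term); and the rate constant `c` between 0.075 (the
#' slowest curve that still plateaus - 95% of the offset decayed - within the
#' model's 0-40-year age domain) and 2 per year.
#'
#' @param a Length-2 numeric: bounds on the final AL (mm).
#' @param intercept Length-2 numeric: bounds on the age-0 AL `a + b` (mm).
#' @param rate Length-2 numeric: bounds on the rate constant `c` (per year).
#' @return A list with elements `a`, `intercept`, `c`.
#' @export
growth_bounds <- function(a = c(18, 28), intercept = c(14, 22),
                          rate = c(0.075, 2)) {
  stopifnot(a[1] < a[2], intercept[1] < intercept[2],
            rate[1] < rate[2], rate[1] > 0)
  list(a = a, intercept = intercept, c = rate)
}

phi_box <- function(bounds, p) {
  lower <- c(bounds$a[1], bounds$intercept[1], bounds$c[1])
  upper <- c(bounds$a[2], bounds$intercept[2], bounds$c[2])
  if (p == 6) { lower <- rep(lower, 2); upper <- rep(upper, 2) }
  list(lower = lower, upper = upper)
}

# heuristic multi-start grid in the (asymptote, intercept, rate)
# parametrisation: exact heuristics (a0 = max AL + 0.1, intercept from
# b0 = min AL - a0 clamped into the box) with a rate grid for the first three
# starts, deterministic jitter within the box for the rest
build_starts <- function(obs, p, starts, box) {
  a0 <- max(obs$y) + 0.1
  i0 <- a0 + (min(obs$y) - a0)  # = min AL, clamped below
  base <- pmin(pmax(c(a0, i0, 0.3), box$lower[1:3]), box$upper[1:3])
  c_grid <- c(base[3], 0.1, 0.6)
  out <- list()
  for (k in seq_len(starts)) {
    if (k <= 3) {
      ph <- c(base[1], base[2], c_grid[k])
    } else {
      ph <- c(base[1] + rnorm(1, 0, 0.3), runif(1, 15, 21),
              runif(1, 0.08, 0.8))
      ph <- pmin(pmax(ph, box$lower[1:3]), box$upper[1:3])
    }
    if (p == 6) ph <- c(ph, ph)
    out[[k]] <- ph
  }
  out
}

variance_starts <- function(phi, obs) {
  r <- obs$y - phi_curve(phi, obs)
  s2 <- max(var(r), 1e-4)
  c(lsig = log(0.5 * s2 * mean(obs$w)), ltau = log(0.5 * s2))
}

fit_ml <- function(obs, start_list, p, tol, box) {
  f <- function(par) phi_nll(par[1:p], par[p + 1], par[p + 2], obs)
  g <- function(par) phi_nll_grad(par[1:p], par[p + 1], par[p + 2], obs)
  lower <- c(box$lower, -25, -25)
  upper <- c(box$upper, 5, 5)
  ctrl <- list(maxit = 1000, factr = max(tol / .Machine$double.eps, 10))
  runs <- purrr::map(start_list, function(th0) {
    par0 <- c(th0, variance_starts(th0, obs))
    res <- tryCatch(
      optim(par0, f, g, method = "L-BFGS-B", lower = lower, upper = upper,
            control = ctrl),
      error = function(e) list(par = par0, value = Inf, convergence = 99L))
    res
  })
  values <- purrr::map_dbl(runs, "value")
  best <- runs[[which.min(values)]]
  # refine from the best candidate
  best2 <- tryCatch(
    optim(best$par, f, g, method = "L-BFGS-B", lower = lower, upper = upper,
          control = ctrl),
    error = function(e) best)
  if (is.finite(best2$value) && best2$value <= best$value) best <- best2

  par <- best$par
  phi <- par[1:p]
  sigma2 <- exp(par[p + 1]); tau2 <- exp(par[p + 2])
  boundary <- par[p + 2] <= -12
  sigma2_boundary <- par[p + 1] <= -12
  v_hat <- tau2 + sigma2 / obs$w
  J_hat <- phi_jacobian(phi, obs)
  expected_info_vcov <- regularized_inverse(crossprod(J_hat / sqrt(v_hat)))
  vcov <- ml_vcov(f, par, p, c(!sigma2_boundary, !boundary),
                  fallback = expected_info_vcov)
  # L-BFGS-B occasionally reports a line-search failure (code 52) at an
  # active bound even though the optimum is attained; accept the solution if
  # the gradient projected onto the feasible directions has vanished
  gr <- g(par)
  at_lo <- par <= lower + 1e-8
  at_hi <- par >= upper - 1e-8
  gr[(at_lo & gr > 0) | (at_hi & gr < 0)] <- 0
  list(phi = phi, sigma2 = sigma2,
       tau2 = if (boundary) 0 else tau2, tau2_boundary = boundary,
       loglik = -best$value, vcov = vcov,
       converged = is.finite(best$value) &&
         (best$convergence %in% c(0L, 1L) || max(abs(gr)) < 1e-3),
       trace = trace_tbl(values, runs))
}

# covariance of the mean parameters from the inverted observed information,
# computed over the mean parameters plus the interior variance components
# (a variance component pinned at the lower boundary of its log scale
# contributes no curvature and would make the full Hessian singular);
# progressively reduced if inversion still fails; the expected information
# (J' V^-1 J)^-1, which is positive definite whenever the design is, is the
# last resort (needed when an active plausibility bound leaves the observed
# Hessian indefinite)
ml_vcov <- function(f, par, p, v_interior, fallback) {
  idx_sets <- list(c(seq_len(p), p + which(v_interior)))
  if (any(v_interior)) idx_sets <- c(idx_sets, list(seq_len(p)))
  for (idx in idx_sets) {
    fi <- function(th) { q <- par; q[idx] <- th; f(q) }
    H <- tryCatch(pracma::hessian(fi, par[idx]), error = function(e) NULL)
    if (is.null(H) || any(!is.finite(H))) next
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(V)) next
    Vm <- V[seq_len(p), seq_len(p), drop = FALSE]
    if (all(is.finite(Vm)) &&
        min(eigen(Vm, symmetric = TRUE, only.values = TRUE)$values) > 0) {
      return(Vm)
    }
  }
  fallback
}

# inverse of an information matrix with near-null eigenvalues floored, so
# directions the data do not identify get very large (conservative) variances
# rather than a failed inversion
regularized_inverse <- function(M, eps = 1e-10) {
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  lam <- pmax(eig$values, eps * max(abs(eig$values), 1))
  eig$vectors %*% (t(eig$vectors) / lam)
}

fit_wnls <- function(obs, start_list, p, tol, box) {
  f <- function(ph) wnls_objective(ph, obs)
  g <- function(ph) wnls_gradient(ph, obs)
  ctrl <- list(maxit = 1000, factr = max(tol / .Machine$double.eps, 10))
  runs <- purrr::map(start_list, function(ph0) {
    tryCatch(optim(ph0, f, g, method = "L-BFGS-B", lower = box$lower,
                   upper = box$upper, control = ctrl),
             error = function(e) list(par = ph0, value = Inf, convergence = 99L))
  })
  values <- purrr::map_dbl(runs, "value")
  best <- runs[[which.min(values)]]
  phi <- wnls_polish(best$par, obs, box$lower, box$upper)

  r <- obs$y - phi_curve(phi, obs)
  S <- sum(obs$w * r^2)
  n <- obs$n
  sigma2_ml <- S / n
  loglik <- -0.5 * (n * log(2 * pi * sigma2_ml) + n - sum(log(obs$w)))
  J <- phi_jacobian(phi, obs)
  sigma2_hat <- S / max(n - p, 1)
  vcov <- tryCatch(sigma2_hat * solve(crossprod(J * sqrt(obs$w))),
                   error = function(e) matrix(NA_real_, p, p))
  list(phi = phi, sigma2 = sigma2_ml, tau2 = 0, tau2_boundary = TRUE,
       loglik = loglik, vcov = vcov,
       converged = is.finite(min(values)),
       trace = trace_tbl(values, runs))
}

trace_tbl <- function(values, runs) {
  tibble::tibble(start = seq_along(values), objective = values,
                 convergence = purrr::map_int(runs, ~ as.integer(.x$convergence)))
}

#' @export
print.al_growth_fit <- function(x, ...) {
  kind <- if (x$grouped) sprintf("grouped (reference: %s)", x$reference) else "combined"
  cat(sprintf("Weighted nonlinear mixed-effects AL growth fit [%s]\n", kind))
  cat(sprintf("  %d studies; logLik %.3f; AIC %.3f; sigma2 %.4g; tau2 %.4g%s\n",
              x$n_studies, x$loglik, x$aic, x$sigma2, x$tau2,
              if (x$tau2_boundary) " (boundary)" else ""))
  est <- x$parameters
  se <- sqrt(diag(x$vcov))
  for (i in seq_along(est)) {
    cat(sprintf("  %-10s %8.4f  (SE %.4f)\n", names(est)[i], est[i], se[i]))
  }
  if (!x$converged) cat("  WARNING: optimiser did not converge\n")
  invisible(x)
}

#' @export
params_for_group.al_growth_fit <- function(x, group) {
  if (!x$grouped) {
    group <- match.arg(group, "combined")
    p <- x$parameters
    return(growth_params(p[[1]], p[[2]], p[[3]]))
  }
  group <- match.arg(group, c("EA", "nonEA"))
  p <- x$parameters
  ref <- growth_params(p[[1]], p[[2]], p[[3]])
  if (group == x$reference || x$fix_deltas) return(ref)
  growth_params(p[[1]] + p[[4]], p[[2]] + p[[5]], p[[3]] + p[[6]])
}

#' Tidy a growth-curve fit
#'
#' @param x An `al_growth_fit` object.
#' @param conf.level Confidence level for the Wald intervals.
#' @param ... Unused.
#' @return A tibble with one row per mean parameter: `term`, `estimate`,
#'   `std.error`, `statistic` (z), `p.value`, `conf.low`, `conf.high`.
#' @method tidy al_growth_fit
#' @export
tidy.al_growth_fit <- function(x, conf.level = 0.95, ...) {
  est <- x$parameters
  se <- sqrt(diag(x$vcov))
  z <- est / se
  q <- qnorm(1 - (1 - conf.level) / 2)
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se), statistic = unname(z),
                 p.value = 2 * (1 - pnorm(abs(unname(z)))),
                 conf.low = unname(est - q * se),
                 conf.high = unname(est + q * se))
}

#' Glance at a growth-curve fit
#'
#' @param x An `al_growth_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with fit-level summaries.
#' @method glance al_growth_fit
#' @export
glance.al_growth_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, sigma2 = x$sigma2,
                 tau2 = x$tau2, tau2_boundary = x$tau2_boundary,
                 nobs = x$n_studies, converged = x$converged,
                 grouped = x$grouped, method = x$method)
}
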