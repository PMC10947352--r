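#' Asymptotic growth-curve parameters
#'
#' Container for the three parameters of the monoexponential (asymptotic)
#' axial-length growth model \deqn{AL(age) = a + b \, e^{-c \cdot age}.}
#' Parameter `a` is the final AL in mm (horizontal asymptote), `b` is the
#' signed offset such that AL at age 0 equals `a + b` (negative for a growing
#' eye), and `c` (per year) controls curve steepness.
#'
#' @param a Final AL (mm); must be positive.
#' @param b Offset (mm) from the asymptote to the y-intercept; stored signed,
#'   so a growing eye has `b < 0`.
#' @param c Rate constant (per year).
#' @return An object of class `growth_params` (a named list with elements
#'   `a`, `b`, `c`).
#' @examples
#' p <- growth_params(23.60, -5.60, 0.30)
#' predict_al(p, 6:10)
#' @export
growth_params <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1, length(b) == 1, length(c) == 1)
  if (!is.finite(a) || a <= 0) abort("`a` (final AL) must be a positive number.")
  if (a + b <= 0) abort("`a + b` (AL at age 0) must be positive.")
  structure(list(a = a, b = b, c = c), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("<growth_params> AL(age) = %.4g + (%.4g) * exp(-%.4g * age)\n",
              x$a, x$b, x$c))
  invisible(x)
}

#' Grouped growth-curve parameters (reference level plus offsets)
#'
#' Two-level parametrisation of the growth curve with the non-East-Asian
#' (non-EA) group as the reference: the EA curve's parameters are the
#' elementwise sum of the reference triple and a difference triple.
#'
#' @param reference A [growth_params] object: the reference (non-EA) curve.
#' @param delta Numeric vector of length 3 (or named list with `a`, `b`, `c`):
#'   EA minus non-EA parameter differences.
#' @return An object of class `grouped_growth_params`.
#' @examples
#' g <- grouped_growth_params(growth_params(23.54, -4.15, 0.24),
#'                            c(a = 0.15, b = -2.76, c = 0.09))
#' params_for_group(g, "EA")
#' @export
grouped_growth_params <- function(reference, delta) {
  stopifnot(inherits(reference, "growth_params"))
  if (is.list(delta)) delta <- unlist(delta[c("a", "b", "c")])
  stopifnot(is.numeric(delta), length(delta) == 3)
  delta <- setNames(as.numeric(delta), c("a", "b", "c"))
  structure(list(reference = reference, delta = delta),
            class = "grouped_growth_params")
}

#' Extract one group's growth parameters
#'
#' For the reference level (`"nonEA"`) returns the reference triple unchanged;
#' for `"EA"` returns the elementwise sum of the reference and the difference
#' parameters.
#'
#' @param x A [grouped_growth_params] object or a grouped [fit_al_growth] fit.
#' @param group `"EA"` or `"nonEA"` (for fits, also `"combined"` when the fit
#'   is ungrouped).
#' @return A [growth_params] object.
#' @export
params_for_group <- function(x, group) UseMethod("params_for_group")

#' @export
params_for_group.grouped_growth_params <- function(x, group) {
  group <- match.arg(group, c("EA", "nonEA"))
  if (group == "nonEA") return(x$reference)
  growth_params(x$reference$a + x$delta[["a"]],
                x$reference$b + x$delta[["b"]],
                x$reference$c + x$delta[["c"]])
}

#' Predict axial length at given ages
#'
#' Evaluates the asymptotic growth curve `a + b * exp(-c * age)`. The curve
#' equals `a + b` at age 0 and tends to the final AL `a` as age grows large.
#'
#' @param params A [growth_params] object.
#' @param age Numeric vector of ages in years; must be non-negative.
#' @return Numeric vector of predicted AL in mm.
#' @examples
#' predict_al(growth_params(23.60, -5.60, 0.30), 24)
#' @export
predict_al <- function(params, age) {
  stopifnot(inherits(params, "growth_params"), is.numeric(age))
  if (any(age < 0)) abort("`age` must be non-negative.")
  params$a + params$b * exp(-params$c * age)
}

#' Annual axial-length growth rate
#'
#' The forward one-year difference `predict_al(age + 1) - predict_al(age)`,
#' the convention used by growth-chart tables (not the instantaneous
#' derivative, which is available as [instantaneous_rate]). The ratio of
#' successive annual rates is exactly `exp(-c)`.
#'
#' @inheritParams predict_al
#' @return Numeric vector of annual growth rates in mm/year.
#' @examples
#' annual_growth_rate(growth_params(23.60, -5.60, 0.30), 6)
#' @export
annual_growth_rate <- function(params, age) {
  predict_al(params, age + 1) - predict_al(params, age)
}

#' Instantaneous axial-length growth rate
#'
#' The derivative of the growth curve, `-b * c * exp(-c * age)` (mm/year).
#' At young ages this exceeds the forward annual difference of
#' [annual_growth_rate] because the curve decelerates within the year.
#'
#' @inheritParams predict_al
#' @return Numeric vector of instantaneous rates in mm/year.
#' @export
instantaneous_rate <- function(params, age) {
  stopifnot(inherits(params, "growth_params"), is.numeric(age))
  if (any(age < 0)) abort("`age` must be non-negative.")
  -params$b * params$c * exp(-params$c * age)
}

#' Published growth-curve parameters
#'
#' The fitted parameter triples of the combined, East-Asian (EA) and
#' non-East-Asian growth curves as printed in the source meta-regression,
#' shipped as a plain-text fixture (`extdata/published_params.json`). The
#' printed curves show `b` as a subtracted positive number; here it is stored
#' signed (negative).
#'
#' @param group One of `"combined"`, `"EA"`, `"nonEA"`.
#' @return A [growth_params] object.
#' @examples
#' predict_al(published_growth_params("combined"), 24)
#' @export
published_growth_params <- function(group = c("combined", "EA", "nonEA")) {
  group <- match.arg(group)
  path <- system.file("extdata", "published_params.json", package = "algrowth",
                      mustWork = TRUE)
  all <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- all[[group]]
  growth_params(p[["a_mm"]], p[["b_mm"]], p[["c_per_year"]])
}
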