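---
title: "Weighted nonlinear meta-regression of axial-length growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted nonlinear meta-regression of axial-length growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(algrowth)
```

## The problem

Axial length (AL) — the front-to-back length of the eye in millimetres — is
the main biometric determinant of refractive error, and normative AL growth
charts for emmetropic eyes are a practical tool for flagging children on a
myopic trajectory. Individual-level longitudinal data above age 6 are scarce,
but many cross-sectional studies report the mean and SD of AL for their
emmetropic subgroup. `algrowth` implements an aggregate-data meta-regression
that pools such study-level summaries into ethnic-specific and combined AL
growth curves, compares East-Asian (EA) and non-EA emmetropes, and emits
age-specific AL and annual-growth-rate tables.

## The model

Each eligible study arm contributes one observation: its mean AL $y_i$ at
mean age $x_i$. The mean curve is the three-parameter asymptotic
(monoexponential) growth model

$$\mathrm{AL}(x) = a + b\,e^{-c x},$$

where $a$ is the final AL (the horizontal asymptote, mm), $b$ the signed
offset from the asymptote to the age-0 intercept ($a + b$ is the model's AL
at birth; $b < 0$ for a growing eye), and $c$ (per year) the rate constant.
The *annual growth rate* reported in the growth table is the forward one-year
difference $\mathrm{AL}(x+1) - \mathrm{AL}(x)$, the convention of published
AL growth charts; successive annual rates decay by exactly $e^{-c}$. The
instantaneous derivative $-bc\,e^{-cx}$ is exposed separately
(`instantaneous_rate()`) and is noticeably larger at young ages (0.28 vs 0.24
mm/year at age 6 for the combined curve), which is why the table convention
matters.

Studies differ enormously in precision, so each study receives the weight

$$W_i = \frac{1}{\mathrm{norm}(SE_{AL})_i + \mathrm{norm}(SE_{age})_i + 0.2},$$

where `norm` is min–max normalisation across the studies entering the fit
(so both standard errors contribute on a common 0–1 scale) and 0.2 keeps the
weight finite for the most precise study. Weights therefore live in
$[1/2.2, 5]$ and are invariant to rescaling either SE vector. When every
study is equally precise the normalised SEs are defined as 0 and all studies
share the maximal weight — equal precision, equal influence.

Ethnicity enters as a two-level grouping with non-EA as the reference: the EA
curve's parameters are the reference triple plus offset parameters
$(\Delta a, \Delta b, \Delta c)$. The offsets are estimated directly, so Wald
tests of ethnic differences ($z = \hat\Delta / SE$, two-sided normal
p-values, 95% CIs with the 1.959964 quantile) read straight off the fit's
covariance. The three contrasts are reported without multiplicity adjustment,
matching the practice of reporting three raw p-values.

### Likelihood

With one summary observation per study, a study-level random intercept on the
asymptote with variance $\tau^2$ collapses into the marginal model

$$y_i \sim N\!\big(f(x_i;\theta_{g(i)}),\; \tau^2 + \sigma^2 / W_i\big),$$

i.e. the weights act as a residual variance function and $\tau^2$ absorbs
between-study heterogeneity. This is the only random-effects placement that
is identifiable with one observation per study, and it mirrors standard
weighted nonlinear mixed-effects practice. Estimation is by maximum
likelihood (not REML), so AIC comparisons between the combined and grouped
fits and the Wald tests are mutually coherent; $\sigma^2$ and $\tau^2$ are
optimised on the log scale, and a $\hat\tau^2$ that runs to the boundary is
reported as 0 with a boundary flag. Note that $\sigma^2$ and the weights are
confounded up to a common scale factor, so only $\sigma^2/W_i$ is
interpretable.

### Optimisation and the plausibility box

The negative log likelihood is minimised by multi-start L-BFGS-B with
analytic gradients (default 8 starts: the heuristics $a_0 = \max y + 0.1$,
$b_0 = \min y - a_0$ with rate starts $\{0.1, 0.3, 0.6\}$, plus jittered
starts derived deterministically from the user's seed), a convergence
tolerance of 1e-9 on the objective, and the parameter covariance from the
inverted numerical Hessian at the optimum (reduced to the interior variance
components when one sits on its boundary, with the expected information
$(J^\top V^{-1} J)^{-1}$ as a final fallback).

One numerical property of asymptotic regression deserves emphasis: when a
corpus carries little information about the bend of the curve (few young
studies, or heterogeneity large relative to the curvature), the likelihood
can increase without bound along a ridge of biologically impossible curves —
$b \to -\infty$ with large $c$ (a spike that interpolates the youngest
study), or $a \to \infty$ with $c \to 0$ (a straight line). The maximum
likelihood estimate then fails to exist in the interior. The optimiser is
therefore constrained to a plausibility box, applied to each fitted curve in
the interpretable parametrisation (asymptote, age-0 intercept, rate):

* final AL $a \in [18, 28]$ mm — the same window used to reject implausible
  AL summaries at read time;
* age-0 intercept $a + b \in [14, 22]$ mm — a liberal window around the
  newborn eye (about 17 mm at term);
* rate $c \in [0.075, 2]$ per year — the lower limit is the slowest curve
  that still plateaus (95% of the offset decayed) within the model's
  0–40-year age domain.

Interior optima — every well-identified corpus — are untouched; the box only
prevents degenerate escapes. With `random_effects = FALSE` the model reduces
to weighted nonlinear least squares ($\tau^2 = 0$, $\sigma^2$ profiled out),
solved by the same multi-start search plus a damped Gauss–Newton polish; on a
well-posed corpus it agrees with an independent Levenberg–Marquardt solver to
about 1e-7 relative error.

### Confidence bands

Prediction bands in `predict_with_ci()` and `growth_table()` use the
first-order delta method: $\mathrm{var}(\hat{\mathrm{AL}}) = g^\top \Sigma g$
with $g$ the gradient of the curve in the fit's parametrisation (for the
non-reference group the chain rule makes the gradient repeat across the
reference and offset blocks). The published table's CI construction is not
stated, so these bands are this package's choice; a parametric-bootstrap
oracle in the test suite guards the propagation. The delta method is a local
linearisation: with very uncertain $(b, c)$ — small corpora — it
underestimates band width, which is one reason the growth table should be
read jointly with the fit's convergence and precision diagnostics.

## Screening and imputation

Eligibility mirrors the meta-regression's inclusion rules, applied in a fixed
order so reason codes are reproducible: optical biometry (ultrasonography is
an exclusion); the study's emmetropia definition contained in −0.50 to
+1.25 D spherical equivalent; a usable age summary (a whole-sample age is
accepted only when the whole-sample age range is at most 3 years — this is
checked before the age-dependent rules, which cannot be evaluated without a
trusted age); cycloplegic refraction unless mean age is 20 years or older;
mean age within 6–30 years; and an emmetrope-specific AL summary present.
Ineligibility is a decision with a reason code, never an error.

Studies reporting medians instead of means are imputed with the
sample-size-adjusted normal-quantile formulas of Wan et al. (2014): from
median and range, from median and IQR, or from all five order statistics
(where the SD is the average of the range- and IQR-based estimators). The
formulas are exactly unbiased only for normal data; the test suite verifies
calibration (mean within 1%, SD within 5%) over simulated normal studies at
n = 15, 50 and 200.

## The synthetic-data generator

Because the extracted corpus is external, every stage is validated against a
generator that emulates the study conditions: 16 EA and 12 non-EA study arms
(the published corpus size), study sizes drawn log-uniformly between 20 and
600 eyes (mimicking the right skew of real study arms), study mean-age
centres spanning 6.5–23.1 years, a study-level random intercept on the
asymptote (default SD 0.2 mm), individual AL noise (default SD 0.6 mm), and
individual ages Normal(centre, 1 year) truncated at 0 by resampling. The
default true curves are the published EA and non-EA triples. Records
summarise their simulated eyes as mean±SD, median+IQR or median+range, so the
imputation path can be stress-tested end to end.

Two generator choices merit explanation. First, age centres are drawn
*stratified* — one centre per equal-width stratum of the age range, shuffled —
rather than iid-uniform, so every corpus actually spans the configured range
the way the source corpus's mean ages span 6.5–23.1 years; iid draws
frequently produce corpora with no study below age 9, for which $(b, c)$ is
essentially unidentified. Second, the random effect sits on the asymptote
only, matching the estimation module's assumed structure; this symmetry is
what makes clean recovery tests possible. The generator does *not* emulate
several features of real corpora — non-normal AL distributions, correlated
emmetropia definitions and ethnicity, unequal emmetropia windows, sex
composition — so passing recovery tests demonstrate internal consistency of
the pipeline, not robustness to those real-world complications.

Under the default conditions (28 studies), the suite's calibration runs show
the asymptote and rate constant are recovered with negligible bias and
Wald-CI coverage near nominal, while the offset $b$ — which requires
extrapolating the curve 6.5 years below the youngest data — is estimated
with large, right-skewed uncertainty, and its symmetric Wald interval covers
the truth in somewhat fewer than 90% of corpora. That is a real property of
Wald inference on this parameter at this corpus size, not an implementation
artefact (coverage approaches nominal as the number of studies grows), and is
worth remembering when reading published CIs for $b$-like parameters.

## Degenerate inputs and numerical conventions

* Min–max normalisation of a constant SE vector returns all zeros (weights
  all 5).
* `sd = 0` summaries are legal (a noiseless study); imputation from spread
  statistics requires $n \ge 2$.
* Fits require at least 3 studies at 3 distinct mean ages; grouped fits
  require both groups present.
* All intervals use the normal quantile 1.959964; presentation rounding is
  half-away-from-zero to 2 decimals, applied only at the serialisation layer
  (`format_growth_table()`).
* Signed dioptre columns accept both the ASCII hyphen and the Unicode minus.
* Every pipeline run (`run_simulate()`, `run_screen()`, `run_fit()`) writes a
  manifest (seed, config, package version, paths) sufficient to reproduce its
  outputs; `run_fit()` output is byte-identical across reruns with the same
  seed, timestamps excepted.

### Calibration of the ethnic contrasts

Null simulations (both groups generated from the same curve) show the
$\Delta c$ Wald test is *conservative* at the default corpus size: it
rejects at the 5% level in roughly 1% of corpora, and remains somewhat
conservative even at 100 studies per group. Two structural features of the
method drive this. First, the precision weight is bounded in $[1/2.2, 5]$
while the true precision of study means (sizes 20–600 eyes) spans a far wider
range, so the model's variance function overstates the variance of exactly
the large studies that pin down $c$; the reported SEs inherit that
overstatement. Second, the two groups' estimates are positively coupled —
through the shared $\hat\sigma^2, \hat\tau^2$ and the corpus-wide min–max
normalisation of the weights — which shrinks the spread of the *difference*
$\widehat{\Delta c}$ below what the likelihood-based SE implies. The test
therefore controls its type I error with room to spare, at some cost in
power; single-group coverage is close to nominal (the combined fit's
rate-constant CI covers ~94–95%).

## Problem sizes used by the validation suite

The suite's stochastic checks use 100 replicate corpora for parameter
recovery, 1000 corpora for the null calibration of the rate-constant
contrast, 1000 simulated studies per scenario and sample size for imputation
calibration, and 2000 parametric bootstrap draws for the confidence-band
oracle. These sizes give Monte-Carlo standard errors comfortably inside the
tolerances they check.

## Known limitations

* Aggregate-data regression cannot see within-study age–AL structure; a
  study's mean AL at its mean age is treated as a point on the curve (the
  Jensen gap from averaging a concave curve over a study's age spread is
  ignored, as it is in the source method).
* The offset parameter $b$ (and hence the age-0 intercept) is an
  extrapolation artefact: no data below age 6 constrain it, and its CI should
  be read with the coverage caveat above.
* With one observation per study, $\sigma^2$ and $\tau^2$ separate only
  through the weight structure; corpora with near-constant weights identify
  only their sum, and $\hat\sigma^2$ frequently sits at its boundary. The
  mean-curve estimates are unaffected.
* The Wald test on $\Delta b$ inherits $b$'s weak identification; its null
  calibration is less reliable than $\Delta c$'s.
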