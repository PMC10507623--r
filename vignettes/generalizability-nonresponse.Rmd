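---
title: "Generalizability analysis of rater-nested evaluation data under unit non-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalizability analysis of rater-nested evaluation data under unit non-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtnest)
```

## The measurement problem

Online teaching evaluations ask every enrolled student (a *rater*, r) to
score their course-instructor (the *person* or object of measurement, p) on
a common set of items (i).  Different students rate different instructors,
so raters are nested in persons; every rater answers every item, so items
are crossed with both.  The resulting design is the two-facet partially
nested random design (r:p) × i, and it is almost always *unbalanced*: class
sizes differ, and unit non-response — a student skipping the survey entirely
— thins each class by a different amount.  Because submission systems refuse
incomplete forms, missingness is always a whole rater, never a single item.

The observed score decomposes into a grand mean and five independent
zero-mean random effects,

$$X_{pri} = \mu + a_p + b_i + c_{pi} + d_{r:p} + e_{pri},$$

with variances $\sigma^2_p$ (instructor), $\sigma^2_i$ (item),
$\sigma^2_{pi}$ (instructor-by-item), $\sigma^2_{r:p}$ (rater within
instructor) and the residual $\sigma^2_{(r:p)i,e}$, in which the
rater-by-item interaction is confounded with all remaining error.  The
G-study estimates these five components; the D-study projects them onto
mean scores over hypothetical numbers of raters $n'_r$ and items $n'_i$ to
ask the practical question: *how many respondents does a class need before
its mean rating is reliable?*

## G-study: analogous ANOVA for the unbalanced design

`gstudy()` estimates the components by analogous ANOVA (Henderson's Method
1).  `uncorrected_totals()` computes the quadratic forms $T_\mu, T_p, T_i,
T_{pi}, T_r, T_{pri}$ (squared totals over the number of observations each
total aggregates), `ss_decomposition()` turns their differences into the
five sums of squares, and `ems_coefficients()` supplies the *exact*
expectation of each SS under the observed rater counts $n_{r(p)}$.  The
unbalance enters only through the k-coefficient $\bar r = \sum_p
n_{r(p)}^2 / N$; the full coefficient matrix is documented on the
`ems_coefficients()` help page.  `solve_components()` solves the resulting
5 × 5 linear system, which is nonsingular for every valid design
($n_p \ge 2$, $n_i \ge 2$, at least one class with two raters).

Three derivation details deserve mention:

* **The EMS cross term.**  In the balanced special case the expected mean
  square for persons is $n_r n_i \sigma^2_p + n_r \sigma^2_{pi} + n_i
  \sigma^2_{r:p} + \sigma^2_{res}$.  Some published summaries of this
  design omit the $n_r\,\sigma^2_{pi}$ term; the standard derivation
  includes it, and so does this package (the tests verify the balanced
  rows against mean-square differencing and against `aov()`).
* **Negative estimates** arise whenever a true component is near zero.
  They are clipped to 0 *after* solving, flagged, and the raw solutions
  kept in the `raw` attribute; percentages and all D-study projections use
  the clipped values so that error variances stay nonnegative.  Clipping
  introduces a small positive bias near the boundary, which is why the
  unbiasedness checks in the test suite use the raw solutions.
* **Estimator choice.**  Analogous ANOVA was chosen over REML because it
  is closed-form, exactly unbiased (before clipping) under any unbalance,
  and reproducible without iterative convergence concerns.  A REML
  estimator would be a natural extension but is out of scope.

Sums of squares are accumulated in double precision; cancellation in the
T-term differences is guarded by a relative tolerance of 1e-9 (tiny
negative SS are clamped to zero, anything worse is an error).  Degenerate
designs — a single person, a single item, or no class with two raters —
fail with an explicit error rather than a singular solve.

## D-study: error variances, g and phi

For a mean score over $n'_r$ raters and $n'_i$ items,

$$\sigma^2(\delta) = \frac{\sigma^2_{pi}}{n'_i} + \frac{\sigma^2_{r:p}}{n'_r}
  + \frac{\sigma^2_{res}}{n'_r n'_i}, \qquad
  \sigma^2(\Delta) = \sigma^2(\delta) + \frac{\sigma^2_i}{n'_i},$$

$$g = \frac{\sigma^2_p}{\sigma^2_p + \sigma^2(\delta)}, \qquad
  \Phi = \frac{\sigma^2_p}{\sigma^2_p + \sigma^2(\Delta)}.$$

The relative error $\sigma^2(\delta)$ collects the components that
interact with the object of measurement (it governs rank-order decisions);
the absolute error $\sigma^2(\Delta)$ adds the item main effect (it
governs criterion-referenced decisions).  At $n'_r = n'_i = 1$ these
reduce to the undivided single-observation sums; the divided (mean-score)
forms are the ones that answer the class-size question, so they are what
`error_variances()` computes.  Always $\Phi \le g$, with equality exactly
when $\sigma^2_i = 0$.

Two optimization schedules are provided.  `dstudy_curve()` evaluates a
grid of rater counts at fixed items — the default grid walks 10 to 100 in
steps of 10 (a grid cannot start at 0: coefficients are undefined with no
raters).  `nonresponse_schedule()` starts at a full class size and steps
down by the mean per-class non-response count, the schedule that traces
what a typical amount of attrition does to a real class.
`min_raters_for_threshold()` scans a curve for the smallest rater count
whose Φ — the stricter of the two coefficients — reaches the reliability
cutoff.  The default cutoff is 0.90, a conventional bar for high-stakes
uses of evaluation data.  Reports round errors and coefficients to 3
decimal places, mean squares to 2, and percentage shares to 1.

## Screening and response prevalence

`apply_screens()` implements four removal rules, in order: classes with a
single respondent (no between-rater variance), core/general courses
(several instructors' ratings merged under one label), duplicated courses,
and courses flagged inconsistent.  The retained set does not depend on the
rule order; only the report attribution does (a person is reported under
the first rule that caught it).  "Inconsistent" is operationalized
conservatively as flag-driven, optionally augmented by scores outside the
instrument range, since no sharper definition is available.

`compute_ratios()` and `classify_nonresponse()` cover the prevalence side:
received/expected ratios per stratum with a totals row, per-stratum ratios
reported at 2 decimal places and the overall ratio at 3 (matching the
precision such institutional tables are printed at), and a high/low
non-response labelling with the boundary convention that a ratio exactly
at the cutoff counts as low non-response.

## The synthetic generator

No public teaching-evaluation dataset with this structure exists, so
`generate_complete()` draws tables directly from the score decomposition.
Every effect is an independent zero-mean normal with the component's
variance — normality is the conventional G-theory working assumption and
makes the variance targets exact.  The defaults emulate the study
conditions the package was built around:

| knob | default | why |
|------|---------|-----|
| `n_p` | 145 | course-instructors retained after screening |
| `n_i` | 10 | items of the delivery-quality scale |
| rater plan | 2 + Poisson(15.6) per class | mean 17.6 raters/class (2,553 raters across 145 classes) with dispersion, floored at the 2 raters every retained class must have |
| `mu` | 3 | an upper-mid rating on the 1–4 Likert scale, reflecting the positive skew typical of teaching evaluations |
| `components` | (0.150, 0.011, 0.063, 0.250, 1.167) | the motivating dataset's G-study estimates |

Scores are continuous by default; `likert = TRUE` discretizes with
round-half-away-from-zero and clamps to 1–4.  Discretization attenuates
variances (roughly 5–10% at these defaults), so recovery tolerances in
discrete mode must be wider; all calibration-sensitive checks therefore
run in continuous mode.

Unit non-response is applied at whole-rater granularity by
`apply_nonresponse()`.  Two mechanisms are available: MCAR removal with a
fixed probability, and a selection (response-propensity) mechanism in
which each rater responds with probability
$\mathrm{logit}^{-1}(\alpha + \beta u)$, where the latent net utility $u$
mixes the rater's own effect $d_{r:p}$ with independent standard-normal
noise.  The logistic link is the minimal monotone choice; no empirical
propensity estimates exist, so $\alpha,\beta$ are generative knobs, with
$\alpha$ defaulting to $\mathrm{logit}(0.484)$ so that the marginal
response rate matches the overall expected-versus-received ratio of the
motivating study.  With $\beta = 0$ the mechanism reduces exactly to MCAR
with $\pi = 1 - \mathrm{logit}^{-1}(\alpha)$.  What the generator does
*not* emulate: ordinal response styles, covariate-driven propensities
(grades, gender), course-type heterogeneity, or semester-to-semester
dependence — so passing tests demonstrate correctness of the estimator
and the direction of non-response effects, not that real evaluation data
satisfy the model.

`recovery_experiment()` ties the pieces together: generate, remove,
screen, re-estimate, and evaluate g and Φ at the rounded mean observed
rater count.  The simulation scales used by the shipped checks — 500
replications at 200 classes × 50 raters × 10 items for unbiasedness, 200
replications at the 145-class study scale per MCAR rate for the
degradation trend — were chosen to put three Monte-Carlo standard errors
comfortably below the effect sizes being verified.

## Numerical conventions and edge cases

* Ties and boundaries: a response ratio exactly at the classification
  cutoff is low-non-response; `min_raters_for_threshold()` uses Φ ≥
  threshold; the Likert rounder takes 2.5 to 3 (half away from zero).
* A non-response step at least as large as the class size degenerates the
  schedule to the single full-class point, with a warning.
* Removing every rater yields a `NULL` observed table and a roster of
  zeros, not an error; a replication whose screened table is degenerate is
  recorded as failed, not fatal.
* Rerunning any pipeline or generator call with the same configuration and
  seed reproduces its artifacts byte for byte.

## Known limitations

Only the (r:p) × i design is supported — no fixed facets, no other
nesting structures, no multivariate extensions, and no confidence
intervals on components.  The analogous-ANOVA estimates, while unbiased,
can be noisy for small numbers of classes; with printed, 3-decimal inputs
the D-study cells inherit that rounding, which is why comparisons against
published grids should allow one unit in the last printed digit.
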