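---
title: "Methods: probabilistic selection-bias analysis with deceased controls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic selection-bias analysis with deceased controls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qbaselect)
```

## The design and its central difficulty

`qbaselect` supports case–control analyses of cause-of-death cohorts in
which both cases and controls are decedents. The motivating design: cases
are firearm suicide decedents among legal handgun purchasers (ICD-10
underlying cause X72–X74), controls are purchasers who died as
motor-vehicle-crash occupants or drivers (a closed ICD-10 V-code list that
structurally excludes intentional and undetermined-intent transport
deaths), and exposures are emergency-department/inpatient diagnoses in the
three years before death.

Deceased controls are the only feasible comparison group when exposure
data exist solely for decedents, but they are not a random sample of the
living source population. If the control-defining cause of death is itself
associated with the exposures (substance use and motor-vehicle crashes, for
instance), exposed controls are over-represented and the observed odds
ratio is biased. The package's central contribution is a summary-level
probabilistic quantitative bias analysis (QBA) that corrects for this.

## The bias model

Let $S_{g,e}$ be the probability that a member of outcome group $g$ with
exposure status $e$ enters the sample. The selection-bias factor is

$$\mathrm{OR}_{select} =
  \frac{S_{case,0}\,S_{control,1}}{S_{case,1}\,S_{control,0}},$$

and the bias-adjusted odds ratio is
$\widehat{\mathrm{OR}}_{adj} = \widehat{\mathrm{OR}}_{obs} \times
\mathrm{OR}_{select}$. When all cases are selected (the default assumption,
appropriate for a census of deaths), the factor reduces to
$S_{control,1}/S_{control,0}$. Because control selection probabilities are
rarely known, `or_select()` also accepts the *benchmark form*: the ratio of
the exposure rate among sampled controls to the rate in a living benchmark
population. Only the ratio matters, so the rates may be supplied in any
common unit.

Each Monte Carlo iteration of `qba_simulate()` draws

$$\exp\!\left(\ln(\widehat{\mathrm{OR}}_{obs}\cdot T) +
  Z\cdot \widehat{SE}(\ln \widehat{\mathrm{OR}}_{obs})\right),
  \qquad T \sim \mathrm{Tri}(0.8m,\ m,\ 1.2m),\ Z \sim N(0,1),$$

with $m$ the $\mathrm{OR}_{select}$ mode. The median of the draws is the
bias-adjusted OR accounting for total error; the 2.5th/97.5th percentiles
form the 95% simulation interval.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `or_select_mode` | — | triangular mode for the bias factor (unitless OR scale) |
| `rel_lower`, `rel_upper` | 0.20 | triangular limits as relative half-widths of the mode |
| `n_iter` | 50,000 | Monte Carlo iterations; values below 1,000 are refused because tail percentiles become unstable |
| `se_ln_or` | derived | SE of the log observed OR; recomputed from the printed 95% CI via `se_from_ci()` when a fit-level SE is unavailable |

Numerical conventions, chosen once and documented here:

- **Triangular limits are on the OR scale** (`mode × 0.8` to `mode × 1.2`),
  not the log scale: "20% lower to 20% higher than the mode" is a statement
  about the OR itself.
- **Percentiles** use linear interpolation between order statistics
  (`stats::quantile` type 7). At 50,000 iterations the choice of percentile
  definition moves the SI bounds by less than Monte-Carlo noise.
- **Sampling** is inverse-CDF for the triangular, so a fixed seed gives
  bit-reproducible draws. The degenerate case `lower = mode = upper` is a
  point mass, allowed so that "no bias uncertainty" is expressible.
- **Batch seeding**: `qba_batch()` derives one seed per exposure from the
  master seed and the exposure label (31-ary string hash modulo
  2147483647), making batch results reproducible and independent of row
  order. Draws are independent across exposures.

## Estimation before adjustment

Observed ORs come from binomial-logistic maximum likelihood (IRLS via
`stats::glm.fit`, tolerance 1e-12, at most 100 iterations) with
heteroskedasticity-consistent sandwich covariance authored in the package:
$B^{-1} M B^{-1}$ with $B = X'WX$ the expected information and $M$ the
outer product of per-observation scores, HC1 small-sample factor
$n/(n-k)$ by default (HC0 available). On a saturated 2×2 design the HC0
robust SE of the log OR equals the Woolf formula
$\sqrt{1/a + 1/b + 1/c + 1/d}$ exactly; the test suite asserts this and
cross-checks the sandwich against an independent brute-force score loop
and against `sandwich::vcovHC`.

Model-hierarchy conventions where the design was genuinely open:

- **Reference levels**: sex = female, marital status = married/partner,
  education = high school or less, urbanicity = large metro. "Unknown" is
  retained as its own level rather than dropped, preserving sample size.
- **Age and death year** enter untransformed (continuous). Because a
  calendar-year covariate makes the intercept legitimately large, the
  separation heuristic (|coefficient| > 15 with exploding SE) excludes the
  intercept; separated terms are reported as non-estimable rather than
  penalized, and the run continues.
- **Wald 95% CIs** on the log-odds scale with $z = 1.959964$.
- Exclusions are applied in a fixed order (age → missing sex → missing
  urbanicity), each person counted once at the first filter that removes
  them, so eligibility reports reconcile exactly.

## Exposure phenotyping conventions

- The lookback window is a **closed interval of calendar years**
  `[death − 3 years, death]`, not 365×3 days; a visit dated exactly three
  years before death is in-window. February 29 anniversaries normalize to
  March 1.
- Code matching strips decimal points from both code and prefix and anchors
  the prefix at the start of the code, so `"2962"` and `"296.2"` are
  equivalent, and matching applies to **any diagnostic field** of a visit.
- Component flags imply their category flag, which implies the any-visit
  flag; categories are *not* mutually exclusive.
- Intent restrictions (unintentional-only drug poisonings) are encoded in
  the code map itself by listing only unintentional external-cause
  prefixes; there is no runtime intent flag.
- The shipped code map (`inst/extdata/codemap_illustrative.csv`) is an
  illustrative stand-in assembled from standard ICD-9-CM groupings. It is
  deliberately a first-class, editable input: analyses of real data should
  substitute a clinically validated list.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws cases and a pre-selection pool of eligible
controls at the real cohort's scale by default (3,862 cases, 1,553 target
controls), with covariate marginals and category-level exposure
prevalences of the order seen in purchaser-decedent data, per-group age
distributions (cases older on average), about 0.9% missing sex/urbanicity,
and a small under-21 fraction (ages truncated at 20) so the eligibility
filter is exercised. Case exposure prevalence is derived from the control
prevalence and the true OR via the logistic identity
$p_1 = \mathrm{OR}\,p_0 / (1 - p_0 + \mathrm{OR}\,p_0)$, so the
population exposure odds ratio equals `true_or` exactly.

`apply_selection()` implements the bias mechanism: each pool control is
retained with probability proportional to
$\prod_e rr_e^{x_e}$, scaled so the expected retained count matches the
target. The induced selection odds ratio for each exposure equals its
`selection_rr`, so the crude OR converges to `true_or / selection_rr` and
feeding the true factor back through the QBA recovers the truth — the key
end-to-end validation.

Simplifications, stated explicitly: exposures are generated independently
across categories (no joint comorbidity structure — the optional
`confounding` toggle, which doubles exposure odds above age 60, is the only
dependence mechanism); covariates are otherwise independent of exposure
and outcome; visit dates are uniform over their window; noise visits carry
a small fixed set of non-mapped codes. Passing tests therefore demonstrate
that the estimators and the bias correction work under the stated
mechanism; they cannot demonstrate robustness to comorbidity clustering,
coding error, or time-varying exposure intensity in real discharge data.

## Validation study conditions

The parameter-recovery study uses 200 replicate cohorts of n = 20,000 at
the real cohort's ~2.5:1 case:control ratio, with one rare, strongly
selected exposure (control-pool prevalence 0.004, true OR 6, selection
ratio 1.71 — the prevalence scale of rare components such as PTSD or
schizophrenia and the selection scale estimated for suicidal
ideation/attempt), QBA at 5,000 iterations per replicate. A rare exposure
is the informative regime for coverage: the QBA simulation interval is
intentionally conservative when the bias parameter is known exactly
(the triangular prior adds spread the estimator does not need), and for
common exposures the sampling SE is so small relative to that spread that
SI coverage approaches 1. At this design point a closed-form calculation
puts true SI coverage near 97%, squarely inside the 90–99% acceptance
band, while the naive ORs exhibit the predicted bias factor
$1/\mathrm{OR}_{select}$. These problem sizes (and the 2×2 oracle fixtures
built from the published descriptive counts) were chosen as the smallest
scales at which the Monte-Carlo error bands are decisive.

## Known limitations

- The QBA is summary-level: it adjusts one OR at a time and cannot restore
  joint inference across exposures.
- The benchmark form of $\mathrm{OR}_{select}$ equates a rate ratio with a
  selection-probability ratio, which is exact only for rare exposures; for
  common exposures it is an approximation, inherited from the design.
- The all-cases-selected assumption is the default; the full
  four-proportion form is available but rarely identifiable in practice.
- No misclassification or unmeasured-confounding bias models are included;
  the package models selection bias only.
- The record linkage that produces the person table is out of scope; the
  pipeline starts from linked person and visit tables.
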