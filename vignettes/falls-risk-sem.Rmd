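---
title: "Modelling falls risk from binocular visual fields: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling falls risk from binocular visual fields: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivfsem)
```

## The scientific problem

Falls are a leading cause of injury in the elderly, and glaucoma — with
its progressive visual-field loss — is a plausible but contested risk
factor. The difficulty is that the two facets of visual function,
visual-field damage and visual acuity (VA), are strongly correlated, so
testing them one at a time misattributes shared variance. The approach
implemented here estimates a single latent *Glaucomatous Damage* factor
from seven visual indicators and models the risk of falling as a second
latent construct driven jointly by that factor and by systemic
covariates, so each input is assessed conditional on the others.

This vignette documents the modelling choices, the numerical design,
what the synthetic-data generator does and does not emulate, and the
known limitations. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` compute.

## The integrated visual field

Perimetry is monocular, but people fall with both eyes open. The
binocular integrated visual field (IVF) is built by `integrate_vf()`:
the left eye's 24-2 total-deviation grid is mirrored horizontally into
right-eye format — which makes the two physiological blind spots
coincide, leaving exactly 52 overlapped locations — and each IVF
location takes the maximum (best) TD of the two eyes. Two consequences
are asserted as invariants: the IVF dominates both monocular fields
pointwise, and improving any monocular point can never worsen any IVF
summary.

`summarize_ivf()` splits the field at the central ten degrees. The
default central set is the 16 locations with $|x|, |y| \le 9$ — the
24-2 points that fall inside the 10-2 test pattern's footprint. Crossed
with the superior/inferior hemifields (the 24-2 has no points on the
horizontal midline, so the split is total; this is asserted, not
assumed) this gives regions of 18/8/8/18 points, and the whole-field
IVF mean deviation is identically their point-count-weighted mean. The
central mapping is an argument, not a constant: published region
figures are images, and a 12-point alternative can be swapped in
without touching the code.

Total deviations are accepted on $[-40, 15]$ dB and are not clipped or
floored beyond that instrument range: no published handling of floor
values exists for this analysis, so none is invented.

## The comparison battery

`build_comparison_table()` reproduces the standard cohort-table
battery, with three deliberate conventions:

* **Chi-square without continuity correction.** Recomputing the
  published group-comparison p-values from their printed counts (0.002
  for gender in the injurious split, 0.10 for diabetes, 0.69/0.64 for
  hypertension) succeeds with the uncorrected Pearson statistic and
  fails with the Yates correction; the corrected variant stays
  available behind `correct = TRUE` for sensitivity analysis.
* **Welch as the default unpaired t.** The printed age comparison
  (66.8 ± 11.5 vs 64.0 ± 10.4, 55 vs 310) gives p ≈ 0.10 under Welch
  and ≈ 0.07 under the pooled-variance Student test; Welch is the
  default and Student sits behind a flag. A summary-statistic entry
  point (`t_test_from_summary()`) exists precisely for such checks.
* **Fisher's two-sided rule by point probability.** The two-sided p is
  the sum of hypergeometric probabilities not exceeding that of the
  observed table — the common software default — and is verified in the
  tests against exhaustive enumeration of every margin-fixed table with
  total ≤ 12. A table with a zero margin carries no information and
  returns p = 1 by convention.

No multiplicity adjustment is applied, matching the univariate-table
tradition the battery reproduces.

## The structural equation models

### Specification

`sem_model()` parses a small path syntax (`=~` loadings, `~`
regressions, `~~` covariances, `1*x` fixes) into RAM form: all observed
and latent variables stacked into one vector, directed coefficients in
$A$, residual variances/covariances in $S_0$, and

$$\Sigma(\theta) = F\,(I - A)^{-1} S_0 (I - A)^{-\top} F^\top$$

the implied covariance of the observed subset. The preconfigured
`falls_model()` has *damage* loading on the four regional mean TDs, the
whole-field MD and better/worse-eye VA, and *risk* regressed on eight
systemic covariates plus *damage*, pinned to the binary outcome by a
unit loading with zero residual (a MIMIC-style single-indicator
latent).

Identification: every exogenous latent has its variance fixed to 1 with
all loadings free (natural when the data are standardized);
single-indicator latents are identified by their fixed loading. The
remaining sign indeterminacy is resolved after fitting by flipping each
latent so its first loading is non-negative — $F_{ML}$ is invariant
under the flip. Exogenous observed variables get a saturated free
variance/covariance block, whose ML solution is the sample values, so
the model's degrees of freedom count only substantive restrictions. The
directed graph must be acyclic, and free parameters may not exceed
$p(p+1)/2$.

The published path diagram leaves one reading ambiguous: whether the VA
coefficients are measurement loadings on *damage* or direct structural
paths into *risk*. The default treats them as loadings, per the
description of the measurement model; `direct_va_paths = TRUE` adds the
two direct regressions for the alternative reading.

### Estimation

`fit_ml()` minimises $F_{ML}$ by quasi-Newton iteration (`nlminb`, 500
iterations cap, two-pass polish). Start values are loadings 0.5, paths
0, residual variances half the sample variance, and exogenous moments
at their sample values. Variance parameters are floored at
$10^{-8}\,\mathrm{tr}(S)/p$ so Heywood-type solutions land on a bound
instead of driving $\Sigma$ indefinite.

The gradient is analytic, derived from the RAM algebra: with
$E = \Sigma^{-1}(\Sigma - S)\Sigma^{-1}$, $M = (I-A)^{-1}$ and
$C = M S_0 M^\top$, the derivative with respect to an $S_0$ entry is an
element of $M^\top W M$ (doubled off-diagonal) and with respect to an
$A$ entry an element of $2\,C W M$, where $W$ embeds $E$ into the full
variable set. The closed-form gradient was chosen over finite
differences because the simulation experiments refit the 60-parameter
falls model hundreds of times; a dedicated test verifies it against
central differences at $10^{-6}$ tolerance. Convergence requires a
gradient infinity-norm below $10^{-8}$ (relative), or the optimiser's
own relative-progress criterion; anything else is recorded in the
returned convergence block and warned about.

Model chi-square is $(N-1) F_{ML}$ — the $N-1$ multiplier is the
conventional choice where the literature is silent. The CFI baseline is
the independence model with free variances, whose ML discrepancy has
the closed form $-\ln|R|$ with $R$ the correlation matrix; RMSEA
follows $\sqrt{\max(\chi^2 - df, 0)/(df(N-1))}$, reported as 0 with a
`saturated` flag when $df = 0$. Standard errors invert the numerically
evaluated Hessian (Jacobian of the analytic gradient) of
$(N-1)/2\,F_{ML}$; intervals are Wald $\pm 1.96\,SE$. When the Hessian
is singular — routine when the input covariance needed regularisation —
the affected SEs are `NA` with a warning rather than a fabricated
number.

### Singular inputs

When the whole-field MD is computed through the pipeline it is an
*exact* linear combination of the four regional means, so the
16-variable sample covariance is singular. `fit_ml()` detects condition
numbers above $10^{10}$ and applies a logged ridge
$S + \varepsilon\,\mathrm{tr}(S)/p\, I$ with $\varepsilon = 10^{-6}$
before taking $\ln|S|$. The generator's default mode instead draws each
indicator with its own residual (a standard factor model), which keeps
the covariance regular; the `"pipeline"` mode exists specifically to
exercise the ridge path, and `run_pipeline()` logs the event.

### Standardization and the interpretation of Wald intervals

The pipeline standardizes every model variable to mean 0, variance 1
within the analysis sample (`standardize_cohort()`, sample-sd
convention by default; the population-sd convention is a switch, and
fit indices are invariant to it). Binary and ordinal variables are
standardized like continuous ones — a fidelity choice, not an
endorsement: the binary fall indicator is treated as continuous after
standardization, which is exactly what fitting these models with a
normal-theory ML estimator on standardized data entails. Probit-type
link treatment of the outcome is out of scope.

Per-sample standardization has a quiet consequence for inference:
every sample variance is pinned to exactly 1, so standardized loadings
behave like correlations, whose sampling variability is smaller than
the free-scale ML information matrix assumes. Wald intervals for
strong loadings are therefore conservative (empirical coverage near 1
rather than 0.95). The structural coefficients are much less affected.
For engine-calibration experiments the package provides
`standardize_theoretical()`, which standardizes a synthetic cohort by
its known population constants instead; under it the recovery
experiment in the acceptance script observes near-nominal coverage
pooled across all loadings and paths. On real data no population
constants exist, so the pipeline's intervals should be read as
conservative for loadings.

## The synthetic cohort generator

The generator is the package's stand-in for the study sample: 365
subjects by default, a ~15% annual faller rate, and ~40% of fallers
injured. Its defaults are the study conditions, chosen once:

* **Demographics** follow the published cohort marginals: age
  64.4 ± 10.6 years, BMI 22.4 ± 3.0 (height drawn at 160 ± 8 cm and
  weight derived, so BMI is internally consistent), female fraction
  0.425, diabetes 14.5%, hypertension 30.4%, sedative use 2.7%,
  sleep-aid use 3.0%, walking 84.8 ± 94.7 min/day drawn from a gamma
  (non-negative, right-skewed, as daily-activity data are). Covariates
  are drawn independently of each other — real systemic covariates
  correlate (age with hypertension, say), and passing tests here says
  nothing about collinearity behaviour on real data.
* **Measurement truths.** A standard-normal damage factor per subject;
  loadings (severity convention: field indicators negative, VA
  positive) of −0.85/−0.80/−0.80/−0.85 for the regional mean TDs,
  −0.90 for the whole-field MD, and the published VA estimates 0.11
  (better eye) and 0.14 (worse eye). Regional indicators are mapped to
  dB with means/sds in the published range (whole-field −2.1 ± 3.8 dB).
* **Structural truths.** For the injurious model the published
  significant estimates serve as generator truth: gender 0.36 and a
  damage-to-risk coefficient of 0.33, whose product with the −0.85
  inferior-peripheral loading reproduces the published −0.28
  association between inferior-peripheral field loss and injurious
  falls. (The falls-model default keeps all covariate truths at zero
  with a modest damage effect of 0.20, mirroring a cohort in which no
  systemic covariate reached significance.)
* **Outcomes.** A unit-variance latent risk score combines the
  standardized inputs; the fall indicator marks the top
  $\lceil 0.15 n \rfloor$ scores (empirical-quantile thresholding, so
  the configured fraction is hit exactly at any coefficient setting),
  and the injury indicator repeats the construction among fallers.
  Thresholding attenuates linear associations, so configured truths
  are calibrated away: the generator solves the exact projection
  equations (closed form for normal inputs via Stein's identity, and
  for binary inputs by enumeration over the two levels) so that the
  configured value is precisely the linear association an analyst
  recovers between the standardized outcome and input. The
  approximate attenuation factor,
  $\varphi(\Phi^{-1}(1-p))/\sqrt{p(1-p)} \approx 0.65$ at $p = 0.15$,
  is exposed as `fall_scale_attenuation()`.
* **Visual acuity** is drawn per indicator on the logMAR scale
  (0.01 ± 0.03, floored at −0.1, hence mildly skewed toward 0) and the
  pair is then ordered per subject, because better/worse-eye VA are
  order statistics by definition. Ordering two jointly normal
  indicators has closed-form consequences (`implied_va_loadings()`):
  both ordered variables end up with the same implied loading,
  $(\lambda_b + \lambda_w)/2 \big/ \sqrt{1 - (1-\lambda_b\lambda_w)/\pi}$
  (≈ 0.15 at the defaults), and acquire a residual correlation the
  factor model does not carry. This is a deliberate realism feature —
  derived min/max variables in real cohorts do exactly this — and it
  is the main reason a default synthetic cohort does not fit its own
  generating model exactly (RMSEA near 0.05 rather than 0). Recovery
  experiments therefore compare VA loadings against the implied
  values, not the pre-ordering configuration.
* **Monocular fields.** Each eye gets a full 52-point grid built from
  region-level structure (the damage draw, an eye-level shift of sd
  0.3, region noise 0.3, and a −1.5 dB monocular offset so each eye is
  worse than the IVF) plus per-point noise of 1.5 dB re-centred within
  region, making the regional means exact. Point noise is spatially
  independent: real scotomata are spatially coherent, so the fields
  are realistic in their regional statistics, not in their local
  shapes.

Everything derives from one mandatory seed (the field stream is
sub-seeded so cohort-level draws are identical whether or not fields
are generated), and regeneration under the same configuration is
byte-identical.

## Problem sizes used by the tests

The suite fits models at the study's own scale: the recovery experiment
runs 200 replicates of the full 16-variable model at N = 365 (about
half a minute), the permutation-null check runs 100 refits with
shuffled outcome labels, the cross-implementation check compares 20
random one-factor models against `stats::factanal` at $10^{-3}$
tolerance, and the implied-covariance oracle uses $4 \times 10^5$
Monte-Carlo draws. These sizes were chosen to bound Monte-Carlo error
comfortably below the assertion tolerances while keeping the suite
runnable on a laptop in about a minute.

## Known limitations

* The binary outcome is modelled linearly after standardization; no
  probit/logit (WLSMV-type) estimator, no FIML for missing data
  (listwise deletion with a logged count), no multi-group models, no
  modification indices.
* Wald loading intervals under per-sample standardization are
  conservative, as discussed above; a subject-resampling bootstrap
  would be the principled alternative and is a natural extension.
* The injurious-falls analysis conditions on the faller subsample
  (N ≈ 55 against 16 observed variables), where normal-theory
  chi-square and RMSEA are rough; fits there should be read
  qualitatively.
* The generator reproduces means, spreads and the latent structure,
  not extreme ranges, covariate correlations, spatially coherent field
  loss, or survey nonresponse.
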