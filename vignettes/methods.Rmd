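---
title: "ER-specific absolute risk modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ER-specific absolute risk modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erisk)
```

## The modelling problem

Breast cancer comprises etiologically distinct subtypes defined by
estrogen-receptor (ER) expression. Reproductive and anthropometric risk
factors associate differently with ER+ and ER- tumours, and available
chemoprevention acts on ER+ disease only, so a risk model that predicts
ER+ tumour risk specifically can be more useful for prevention decisions
than an omnibus breast-cancer model. `erisk` implements the full
methodology for building and evaluating such models on cohort data:

1. **Cause-specific hazards.** ER+ and ER- tumours are modelled as
   mutually competing causes with piecewise-constant baseline hazards on
   the age time scale; age-band cutoffs sit at 45, 50, 55, 60, 65, 70 and
   75 years, with the first band open below and the last open above.
   Tumours of unknown ER status, primary cancers at other sites and
   deaths from non-cancer causes form a pooled competing-event cause with
   a Gompertz hazard $h(t) = \exp(\alpha + \gamma t)$.
2. **Coefficient sharing.** Each covariate's log hazard ratio is either
   shared across the two ER causes or cause-specific. Sharing is realised
   by design-matrix aliasing in a jointly maximised likelihood — both
   causes' episodes are stacked and a shared covariate contributes one
   column — so a shared coefficient is bit-identical across causes and
   the likelihood-ratio test between sharing structures is a valid nested
   test of etiologic heterogeneity.
3. **Absolute risk.** Fitted hazards are converted to 5-year cumulative
   incidences under competing risks, with external recalibration of the
   baseline hazards for projection onto a different population.
4. **Evaluation.** Fivefold cross-validated discrimination (C-statistic)
   and calibration (expected/observed ratio, risk deciles), and decision
   curve analysis with the applicability-area statistic.

## Likelihood and fitting

Splitting follow-up $[e_i, x_i)$ at the cutoffs gives episodes with
exposure $T$, band $b$ and at most one terminal event. The joint
log-likelihood over causes $k$ is the piecewise-exponential form

$$\ell = \sum_k \sum_i d_{ik}\,(\log \lambda_{k,b(i)} + \beta_k' x_i)
        - T_i\, \lambda_{k,b(i)}\, e^{\beta_k' x_i},$$

which coincides, up to a constant, with a Poisson regression of the
event indicators on the cause-by-band factor with a log-exposure offset.
`fit_piecewise()` maximises it by Newton–Raphson with step-halving,
initialised deterministically at zero coefficients and per-cause crude
log rates, and declares convergence when the gradient sup-norm falls
below `1e-8` (200 iterations maximum). The covariance comes from the
observed information. A band-by-cause cell without events has no finite
MLE; its baseline is pinned to log-hazard $-30$ (effectively zero
hazard) with a warning, and the cell is excluded from the free
parameters. The test suite checks the fitter against an independent
Poisson-GLM oracle on fixtures to $10^{-6}$.

The Gompertz competing-event fit uses the left-truncated likelihood with
the exact cumulative hazard
$H(t_1, t_2) = e^{\alpha}(e^{\gamma t_2} - e^{\gamma t_1})/\gamma$ and
its $\gamma \to 0$ exponential limit, optimised with `optim`
(L-BFGS-B, $\gamma$ bounded in $[-1, 1]$ against overflow). Unknown-ER
tumours are competing events here and never contribute ER-specific
events; under an ER-status missing-at-random assumption this leaves the
ER-specific coefficient estimates unbiased while deflating the tumour
baselines — which is also why external projection re-estimates baselines
on the target population.

Heterogeneity of a covariate is tested by `lrt_heterogeneity()`:
$2(\ell_{\text{free}} - \ell_{\text{shared}})$ on the difference in free
parameter count. The stratum variable (country) is always
cause-specific, and no multiplicity adjustment is applied across
per-covariate tests (results are reported per variable).

## Absolute risk under competing risks

`cumulative_incidence()` partitions the projection interval
$[a, a + h)$ at the cutoffs. Within a segment the tumour hazards
$\lambda_1, \lambda_2$ are constant and the competing hazard is
Gompertz, so the cause-$k$ increment is
$\lambda_k \int_{t_1}^{t_2} S(t)\,dt$ with

$$S(t) = S(t_1)\, e^{-(\lambda_1 + \lambda_2)(t - t_1)}
  \exp\!\left[-B\left(e^{\gamma (t - t_1)} - 1\right)\right],
  \qquad B = e^{\alpha + \gamma t_1}/\gamma.$$

The survival integral is evaluated by expanding the Gompertz factor as a
power series in $B(e^{\gamma s} - 1)$; each term integrates in closed
form, and at the hazard scales arising in this model family
($B(e^{\gamma \Delta} - 1) < 0.5$) truncation at order 15 leaves an
error far below $10^{-12}$, so no numerical quadrature is involved.
Survival chains multiplicatively across segments, the competing-event
probability is the complement, and the projections satisfy
`sum(cause risks) + survival = 1` to $10^{-10}$, monotonicity in the
horizon, and agreement with an adaptive-quadrature oracle to $10^{-8}$
on random parameter draws (all asserted in the tests). A $\gamma = 0$
competing hazard folds into the constant total and is handled exactly.

`recalibrate_baseline()` freezes all coefficients at the source values
and re-estimates each band-by-cause baseline on the target cohort by the
closed-form profile MLE
$\hat\lambda_{k,b} = d_{k,b} / \sum_i T_{i,b} e^{\beta_k' x_i}$; the
Gompertz hazard is refitted on the target. Source stratum coefficients
are dropped by default, since the target's own incidence level is
absorbed by its baselines; this mirrors the elimination of the
derivation cohort's country effects in external projection.

## The synthetic-cohort generator

The package's studies run on synthetic cohorts because individual-level
derivation data of this kind are not redistributable. The generator
emulates the structure the analysis assumes:

* **Covariates** (`generate_covariates()`): entry ages uniform on
  [40, 70); categorical marginals for menopausal status (51%
  postmenopausal), age at menopause, menarche, HRT duration,
  breastfeeding, BMI, alcohol, parity and country; height normal with
  mean 163 cm and SD 6.5 cm, entered per 10-cm increment centred at
  160 cm. Structural dependencies are generated conditionally: age at
  menopause exists only for postmenopausal women, the parity block only
  for parous women, and the BMI-by-menopause code 0–3 is derived, with
  0 meaning premenopausal or postmenopausal with BMI < 25. Where no
  published marginal was available the values were chosen once as
  plausible for a large European cohort of women aged 40–70 and are not
  revisited; they are configurable through `default_covariate_config()`.
* **Ground truth** (`default_true_model()`): the registry's EPIC-style
  log hazard ratios (shared: menopausal status 0.66, age at menopause up
  to 1.41, menarche down to 0.85, HRT up to 1.55, BMI, BMI-by-menopause,
  alcohol; cause-specific: parity block, height 1.19/1.06 per 10 cm,
  country). Baselines rise over the age bands and are scaled so the
  observed crude rates are roughly 175 ER+ and 39 ER- tumours per
  10^5 person-years after 25% of tumours are relabelled unknown-ER, with
  Gompertz competing events ($\alpha = -10.4$, $\gamma = 0.09$) at 5–6
  per 1000 person-years — the order of magnitude of large European
  cohorts of this age range.
* **Events** (`simulate_outcomes()`): the latent first-event time is
  drawn by inverse-CDF sampling of the exact total cumulative hazard,
  segment by segment. Within the segment containing the event the
  crossing equation mixes a linear (piecewise-constant) and an
  exponential (Gompertz) term; rather than evaluating its Lambert-W
  closed form, the implementation brackets the root exactly and solves
  by 60 vectorised bisection steps, which is equivalent at machine
  precision ($\approx 4 \times 10^{-16}$ relative) and immune to the
  overflow the closed form invites. The cause is drawn proportionally to
  the cause-specific hazards at the event age; administrative censoring
  draws a per-subject follow-up uniform on 10–18 years truncated at age
  80 (mean follow-up about 13.5 years). All random numbers are drawn up
  front, so the stream — and hence the cohort — is reproducible under a
  seed regardless of the event pattern.
* **Missingness** (`inject_missingness()`): MCAR or MAR-on-age masking
  at configured per-variable rates; event columns are never masked and
  structural `NA`s are untouched.

What the generator does *not* emulate: correlation of covariates with
entry age (menopausal status is drawn independently of age, so the
age-band baselines absorb all age effects), within-family correlation,
calendar-time trends, or measurement error. Passing recovery tests on
these cohorts therefore demonstrates correctness of the estimators
under the model's own assumptions, not robustness to the
misspecifications real cohorts add.

## Multiple imputation

`impute_chained()` is a chained-equations scheme: random hot-deck
initialisation, then `sweeps` cycles (default 10) of conditional draws —
multinomial-logistic for categoricals, normal-linear with residual-SD
noise for continuous variables, truncated to the observed range so no
impossible values arise. Every conditional model includes the other
covariates, a tumour indicator and log follow-up time. Structural
non-applicability is treated as a valid state, not imputed; when a
parent variable is itself imputed, applicability of its dependents is
re-evaluated every sweep. The `m` imputations (default 5) use seed
offsets `seed + 1 … seed + m`. `pool_rubin()` combines estimates with
total variance $W + (1 + 1/m)B$ and Barnard–Rubin degrees of freedom.
Which variables the conditionals should include is not prescribed
anywhere authoritative; the generic all-covariates form was adopted.

## Validation choices

* **C-statistic:** the comparable-pairs (Harrell-type) definition
  truncated at the horizon, computed through `survival::concordance`
  with competing events censoring observation at their occurrence; the
  tests pin the definition to an exhaustive pair-enumeration oracle.
  Ties in risk count 0.5. The CI is a 200-replicate subject-level
  bootstrap percentile interval.
* **E/O:** expected = sum of predicted risks; observed = raw count of
  target-cause events within the horizon, with an optional
  Aalen–Johansen-adjusted count (`adjust = "aalen-johansen"`) as a
  sensitivity switch for censoring-induced undercount. The CI is the
  log-scale Poisson form $(E/O)\exp(\mp 1.96/\sqrt{O})$.
* **Cross-validation:** five seeded folds differing in size by at most
  one; metrics are computed on the pooled out-of-fold predictions
  (pooling, rather than per-fold averaging, was adopted as the
  convention). If a training fold lacks events of a cause the fold
  assignment is re-randomised once before erroring.

## Decision curves

`net_benefit_curve()` uses the treat-if-risk-$\geq p_t$ convention
(closed at the threshold) on a grid of thresholds in steps of 0.0005 up
to the maximal risk estimate. At the indifference threshold
$p_t B = (1 - p_t) H$, so the implied benefit-to-harm ratio is
$(1 - p_t)/p_t$; `threshold_bh(..., nearest = 5)` also reports it
rounded to the nearest 5, the form used in clinical summaries (0.55% →
180, 2.5% → 40, 4% → 25 — note the rounded figures coincide with
rounding $1/p_t$, an ambiguity flagged but not resolved here). The
applicability area integrates
$NB_{\text{model}} - \max(NB_{\text{all}}, 0)$ by the trapezoidal rule,
reporting the signed below-envelope and above-envelope components and
their sum; when the model outcome is ER+ tumours the treat-all line can
be computed both for ER+ only and for all breast cancer.

## Problem sizes and numerical conventions

The simulation studies use the sizes at which their conclusions are
stable: hazard-ratio recovery on cohorts of 200,000 subjects (about
4,600 ER+ and 1,050 ER- events), the type-I-error study of the
heterogeneity LRT on 500 replicate cohorts of 20,000 subjects with a
single shared binary covariate, quadrature-oracle agreement on random
parameter draws, and cross-validation demonstrations on cohorts of
8,000 with proportionally raised baselines so each fold retains events
of both causes. The acceptance script averages the recovered
menopausal-status hazard ratio and ER+ height effect over five
independent 200,000-subject cohorts: each replicate is a draw of the
same estimand and averaging reports a tighter Monte-Carlo estimate of
it. Ties, degenerate inputs and edge cases follow the conventions
stated above: empty baseline cells pin to $-30$, all-zero hazards give
pure administrative censoring, decile ties break by stable subject
order, and a negative LRT statistic beyond $-10^{-6}$ is treated as an
optimisation failure rather than silently clipped.

## Known limitations

Coefficients and baselines are estimated jointly only within the
piecewise model; the Gompertz cause carries no covariates. The
generator's covariate independence from entry age means confounding by
age is absent by construction. Family history and breast-biopsy
variables are out of scope, as are calendar effects, time-varying
covariates, frailty terms and spline baselines. The C-statistic's
censoring handling and the E/O confidence-interval form follow the
stated conventions; other definitions exist and would give slightly
different numbers on heavily censored data.
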