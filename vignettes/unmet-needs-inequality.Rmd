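---
title: "Measuring and decomposing income-related inequality in unmet health care needs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing income-related inequality in unmet health care needs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unmetci)
```

## The problem

Health systems aiming at universal coverage care not only about how many
people forgo care when they need it, but about *who* forgoes it. An unmet
health care need is a self-reported failure to obtain outpatient or
inpatient care despite a recognised need — because of money ("no money"
as the main reason: a *financially constrained* unmet need) or for any
other reason such as time, travel, perceived service quality or
self-treatment (*non-financially constrained*). The empirical regularity
in middle-income settings is that financially constrained unmet needs
concentrate among the poor while non-financially constrained ones
concentrate among the rich; a natural question is how much of either
gradient is channelled through observable characteristics such as social
health insurance (SHI) enrolment, education, health status or region.

`unmetci` implements the standard measurement toolkit for this question
on respondent-level cohort tables: incidence tabulation, concentration
indices over fractional income ranks with bootstrap intervals and curve
coordinates, and the regression-based decomposition of the index into
per-covariate contributions.

## The concentration index

Respondents are ranked by income. The fractional rank of respondent $i$
is their weighted midpoint position in the income distribution,
$r_i = (2i-1)/(2n)$ with equal weights and no ties; tied incomes share
the midpoint rank of their block. The concentration index of a binary
outcome $y$ with mean $\mu$ is

$$CI = \frac{2}{\mu}\,\operatorname{cov}(y_i, r_i),$$

bounded in $[-1, 1]$, negative when the outcome concentrates among the
poor, zero under an income-unrelated distribution. The concentration
curve plots the cumulative share of the outcome against the cumulative
population share from poorest to richest; the index equals one minus
twice the area under the curve.

Two conventions matter numerically and are fixed package-wide:

* **Population covariance.** The covariance divides by the total weight,
  not $n-1$. This makes the index exactly equal to $1 - 2\times$ the
  trapezoidal curve area and exactly antisymmetric under rank reversal;
  the sample-covariance convention would break both identities by a
  factor $n/(n-1)$. The test suite asserts the curve identity
  exhaustively over all small binary configurations at $10^{-12}$.
* **Midpoint tie handling.** Tied ranking values share one fractional
  rank, which is what keeps the (weighted) mean rank exactly $0.5$ and
  the index well defined under heavily tied incomes.

The ranking variable is the raw deflated income, not its log: ranks are
invariant to monotone transforms, so this choice is cosmetic but pinned
for reproducibility.

### Interval estimation

Published tables of this kind report 95% intervals without stating the
method. The package implements exactly one: a percentile bootstrap
(default $B = 1000$) that resamples respondents with replacement,
*re-ranks incomes within each replicate*, and takes the 2.5th/97.5th
percentiles. The result object records `interval_method` so downstream
tables can never silently misattribute the interval type, and a
delta-method alternative is deliberately not implemented: one auditable
path. Replicates with no cases are dropped; more than 10% degenerate
replicates aborts, since percentiles of a censored replicate set would
be misleading.

## Preparing the cohort

Cohort tables are read against an explicit variable schema (role, type,
levels, reference group per column). Validation applies listwise
deletion on all schema columns and reports the dropped count — survey
sources typically say only that respondents with "too many" missing
values were excluded, so the package makes the simplest reproducible
rule (drop any incomplete row) explicit and visible rather than
guessing a threshold. Binary columns must be strictly 0/1, categorical
values must match declared levels, and incomes must be non-negative;
violations name the row.

Currency variables observed in different survey waves are deflated with
`deflate_to_base()` (`value * cpi[base]/cpi[year]`) before the
`log1_transform()` (`ln(x + 1)`, keeping zero incomes finite); the log
transform is applied after deflation. Categorical covariates enter
design matrices as indicator columns omitting the declared reference
level, in schema order, so repeated builds are byte-identical
regardless of row order.

## The probit engine and marginal effects

The decomposition requires a linear approximation to the binary-outcome
model. The package fits the probit
$P(y_i = 1) = \Phi(\delta + \sum_k \beta_k z_{ki})$ by Newton–Raphson on
the exact log-likelihood: observed-information steps with step-halving,
deterministic start at $\beta = 0$, gradient max-norm tolerance
$10^{-8}$, at most 100 iterations. Standard errors come from the
inverse observed information. Rank-deficient designs fail with the
offending columns named; coefficient paths exceeding 20 on standardized
columns are reported as (quasi-)complete separation rather than
returned as spurious estimates. `stats::glm` with a probit link serves
as an independent cross-check in the test suite (coefficients agree to
$10^{-6}$ relative on randomized fixtures), never as the
implementation.

Marginal effects are evaluated at the covariate means:
$\gamma_k = \phi(\bar z'\hat\beta)\,\hat\beta_k$ — one common density
factor times each coefficient, verified in tests against central finite
differences of the fitted probability. Indicator columns are treated in
the same derivative form rather than as discrete changes: the
decomposition needs a single uniform linearization, and published
decomposition tables make no discrete/continuous distinction in their
marginal-effect column. This is a documented choice, not an assumed
equivalence.

## The decomposition

With the linear approximation
$y_i \approx \delta_{\text{lin}} + \sum_k \gamma_k z_{ki} +
\varepsilon_i$, the concentration index decomposes as

$$CI = \sum_k \frac{\gamma_k \bar z_k}{\mu} C_k +
\frac{GC_\varepsilon}{\mu},$$

where $C_k$ is the concentration index of covariate $k$ over the same
income ranks, $\gamma_k \bar z_k / \mu$ its elasticity, and
$GC_\varepsilon = 2\operatorname{cov}(\varepsilon, r)$ the generalized
concentration index of the residual. Implementation choices:

* The residual is computed from the linearized prediction error with
  the intercept fixed by mean-matching
  ($\delta_{\text{lin}} = \mu - \sum_k \gamma_k \bar z_k$), which makes
  the adding-up identity exact by bilinearity of the covariance. The
  identity is still asserted at $10^{-10}$ on every call, and the
  equivalent route $CI - \sum_k \text{contribution}_k$ is checked
  against it in tests.
* $C_k$ for indicator columns is the plain concentration index of the
  0/1 column (its mean is the level's share) — standard practice for
  this decomposition.
* A centered covariate with $\bar z_k = 0$ has elasticity 0 by
  construction and an undefined own index; its contribution is set to
  zero and the situation is a documented footgun (it hides effects), so
  the synthetic configurations avoid centering.
* Percentage contributions are $100 \times \text{contribution}/CI$:
  same-sign contribution and total index give a positive percentage.
  Near-zero total indices inflate percentages; magnitudes beyond
  $10^4$ warn rather than error.
* `group_rollup()` sums the contributions (and percentages) of the
  indicator columns of one categorical variable. Note that narrative
  aggregates in published work do not always equal the sum of the
  printed per-level cells; the roll-up here is plain summation,
  closing to exactly 100% together with the residual share.

## The synthetic cohort generator

The generator exists so the whole pipeline can be exercised — and its
estimators tested by parameter recovery — without any external survey
files. It is a fully specified probit data-generating process:

* **Income** is log-normal with log-mean 9.0 and log-sd 0.8 (in RMB).
  Household income surveys in this population report a mean near
  10,000 RMB with strong right skew; the log-normal is the standard
  shape, and these parameters put the mean log income near the reported
  8.7 while the arithmetic mean lands near 11,000 RMB — the right order
  and skew, which is what the rank-based estimators care about.
* **Covariates** load on the same standard-normal latent that drives
  income: covariate $=f(a u + \sqrt{1-a^2}\,e)$ with association
  $a$ and independent noise $e$. This shared-latent-index mechanism is
  the simplest one that gives covariates nonzero concentration indices
  $C_k$, which the decomposition needs to be non-trivial. Defaults
  mirror the inpatient-need analysis sample of a large Chinese ageing
  survey: SHI prevalence 0.979 mildly pro-rich ($a = 0.25$), education
  shares (0.29, 0.43, 0.18, 0.10) strongly income-graded ($a = 0.45$),
  urban share 0.37 ($a = 0.40$), chronic disease 0.62 ($a = -0.05$),
  age 63.1 (sd 9.5, $a = -0.10$).
* **Outcomes** are Bernoulli with probability $\Phi(\delta + \sum_k
  \beta_k z_k)$. Slope signs follow the published marginal-effect
  pattern (insurance and income protective against financially
  constrained unmet need; education and urban residence raising the
  non-financial type). The two intercepts and the two income slopes
  were calibrated once against the large-sample oracle so the process
  reproduces the published inpatient study conditions — incidences
  18.7%/15.7% and concentration indices $-0.156$/$+0.035$ — and then
  frozen; they are not tuning knobs. The inpatient (rather than
  outpatient) column was chosen because both outcome types are common
  there, which keeps estimation stable at moderate cohort sizes.
* **Ground truth** comes from `population_truth()`: one large simulated
  population (default 200,000; the recovery tests use 500,000) in which
  incidence and index are evaluated on the exact probabilities
  $\Phi(\eta_i)$, integrating out the Bernoulli draw so the oracle
  carries only covariate-sampling noise. Contribution truths use the
  DGP's own marginal effects at the oracle covariate means — the
  estimand of the linear-approximation decomposition, which is what the
  estimator can be expected to recover. Truths are always computed,
  never typed in.

What the generator does *not* emulate: the survey's multistage sampling
design, panel structure across waves, item nonresponse patterns, or
reporting error in self-assessed needs. Passing recovery tests
therefore show that the estimators are correct for a well-specified
probit world with income-graded covariates, not that the pipeline would
reproduce any particular published table from raw survey files.

## Numerical and testing choices

Problem sizes were chosen to keep the full suite fast while leaving
Monte-Carlo error well below the asserted tolerances: algebraic
identities are checked exhaustively at $n \le 8$ and at $10^{-10}$ to
$10^{-12}$ on simulated cohorts of 1,200–2,000; oracle equivalence uses
20 fixtures of $n = 200$; recovery uses cohorts of 10,000–20,000
against a 500,000-respondent oracle. One caveat is worth stating
plainly: for a binary outcome at incidence $\approx 0.19$, the
concentration-index estimator's sampling spread at $n = 20{,}000$ is
visible in the bootstrap intervals the pipeline itself reports (widths
near $\pm 0.016$), so a *single* cohort's estimate recovers the oracle
truth only to about that precision — the suite therefore also checks
that the mean over independent replicate cohorts closes on the truth,
which is the sharper statement about estimator correctness.

Determinism is a contract throughout: every random step (generation,
bootstrap) takes an explicit seed, seeded code restores the caller's
RNG stream, and re-running a pipeline config reproduces byte-identical
output files.

## Limitations

* The decomposition inherits the linear approximation: contributions
  are defined relative to marginal effects at means, and a different
  evaluation point (e.g. average marginal effects) would shift
  individual contributions while preserving the adding-up identity.
* No survey design weights are applied in the headline decomposition
  (the concentration functions accept weights for standalone use); no
  clustered standard errors are computed.
* Binary-outcome concentration indices are reported unnormalized. The
  attainable range of the plain index shrinks with $\mu$, so indices
  are comparable across outcomes with similar incidence but not across
  very different incidences; normalized variants are intentionally out
  of scope here.
* The bootstrap interval is percentile-based; it is labelled as such
  and should not be read as replicating any specific published
  interval method.
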