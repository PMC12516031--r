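---
title: "Hybrid choice analysis of inclusive health insurance preferences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid choice analysis of inclusive health insurance preferences: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcmdce)
```

## The scientific problem

Complementary inclusive health insurance ("Huimin"-type products in China)
covers catastrophic health spending above a high deductible for a low annual
premium, usually with some degree of government involvement. Enrollment is
voluntary and typically low, and a central question for scheme design is
which product attributes people value and how psychological constructs —
perceived health risk, awareness of the scheme, and perceived value — shape
those preferences.

`hcmdce` implements the full quantitative workflow of a stated-preference
study of such a product: a D-efficient discrete choice experiment (DCE), an
attentiveness screen, scale reliability diagnostics, and joint estimation of
an integrated choice and latent variable (ICLV / hybrid choice) model by
maximum simulated likelihood. Because the original survey data are available
only on request, the package also contains a first-class synthetic-data
generator that reproduces the statistical structure of the study, so that
every stage of the pipeline is testable end to end and the estimator can be
validated by parameter recovery.

## The experimental design

Five attributes describe an insurance profile (`huimin_attributes()`):
annual premium (130/170/210 RMB, linear, utility-decreasing), government
involvement (purely commercial / moderate / strong, dummy-coded against
commercial), deductible (120/150/180 thousand RMB, linear per 10 000 RMB,
decreasing), reimbursement rate (50/65/80 %, linear, increasing), and a
value-added service package (basic drug discounts against three expanded
packages, dummy-coded against basic). The full factorial holds
`3*3*3*3*4 = 324` profiles.

Each choice task shows two insurance profiles plus an opt-out ("buy
neither"). `generate_design()` selects 24 tasks in 4 blocks of 6 by
coordinate exchange: random starting designs are improved one attribute at a
time, accepting only strict reductions of the D-error

$$D = \det\{I(\beta)\}^{-1/K},$$

the determinant-scalarized information matrix of the conditional logit over
the design, with $K$ utility parameters (the 8 coded attribute columns plus
the opt-out constant). Priors default to zero (a utility-neutral design);
the opt-out enters each task with utility equal to its prior.

Three practical constraints shape the search:

* **Dominance screening.** A task in which one profile is at least as good
  on every attribute teaches nothing about trade-offs; such pairs are
  rejected during the exchange (`screen_dominated = TRUE`). The dominance
  order treats basic service packages as worse than any expanded package,
  expanded packages as mutually incomparable, and commercial operation as
  worse than either degree of government involvement (moderate and strong
  tie, as both carry the same hypothesized direction).
* **Level balance and coverage.** Every attribute level must appear in
  every block. The exchange therefore keeps each level's occurrence count
  within one unit of perfect balance (and in at least `n_blocks` distinct
  tasks) — the convention of level-balanced efficient designs — because the
  unconstrained utility-neutral optimum concentrates linear attributes on
  their extreme levels, leaving middle levels too scarce for any block
  assignment to cover.
* **Blocking.** Tasks are assigned greedily to blocks to minimize squared
  deviation from perfect level balance (ties to the lowest block id),
  followed by a pairwise-swap repair in which coverage holes dominate the
  balance objective.

A quality-control (QC) task (`make_qc_set()`) pairs the best profile under
the hypothesized signs with the worst; it is flagged, excluded from D-error
and from the estimation likelihood, and used only for the attentiveness
filter. On degenerate toys (two binary attributes) the dominance screen
leaves a single admissible pair type and no identified design exists; the
screen can be switched off there, which recovers the classical orthogonal
benchmark that exhaustive search finds.

## The data-generating process

The generator mirrors the model the estimator fits; its defaults are the
study conditions.

**Covariates** (`sample_covariates()`): gender (51.4 % female), urban
residence (70.7 %), three age bands (21.0 / 51.0 / 28.1 %, youngest as
reference), college education (20.4 %), above-average income (30.6 %), ever
bought private insurance (46.7 %), and catastrophic disease experience in
the household (16.99 %) — the descriptive shares of the study's valid
sample. Education and income are sampled for the descriptives table but, as
in the study's tables, enter neither the structural nor the choice model.
The published age-band boundaries are inconsistent between the methods text
and the results table; the package treats the bands as ordered labels and
never uses cut ages numerically.

**Latent constructs** (`simulate_latents()`): with covariate vector $z$ and
independent standard-normal disturbances,

$$\mathrm{HR} = \gamma_{HR}'z + \eta_1,\qquad
  \mathrm{AW} = \gamma_{AW}'z + \lambda_{HR\to AW}\mathrm{HR} + \eta_2,\qquad
  \mathrm{VAL} = \gamma_{VAL}'z + \lambda_{HR\to VAL}\mathrm{HR}
        + \lambda_{AW\to VAL}\mathrm{AW} + \eta_3,$$

the sequential risk–awareness–value structure of insurance decision theory.
Disturbance variances are fixed at one and there are no structural
intercepts; location and scale are absorbed by the measurement thresholds
and loadings.

**Indicators** (`simulate_indicators()`): eleven five-point Likert items
(five health-risk, three awareness, three value) follow an ordered logit,
$P(Y_i \le k) = \Lambda(\tau_{ik} - \zeta_i \mathrm{LV}_{g(i)})$, with
loadings from the published measurement model. The thresholds are not
published; the package documents the default $(-2, -0.5, 0.5, 2)$ for every
item and records this provenance on the parameter object. Scale means
therefore need not match the published ones, while covariance-driven
quantities (Cronbach's alpha, composite reliability, AVE) do, because they
depend on the loadings.

**Choices** (`simulate_choices()`): each respondent is assigned one design
block and answers its six tasks plus the QC task. Utilities are

$$V_{ntj} = \textstyle\sum_k \beta_{nk} x_{jk}
          + \sum_m \theta_m w_{nm} x_{j,k(m)},\qquad
  V_{nt,\text{opt-out}} = \delta + \varphi' \mathrm{LV}_n,$$

with respondent-level random coefficients
$\beta_{nk} = b_k + \sigma_k \xi_{nk}$ drawn once and shared across the
panel (independent across coefficients; no correlation matrix), interaction
shifts $\theta$ from the 21 published terms (unpublished candidates are
zero), and multinomial-logit choice. Interactions shift the mean of a
coefficient, not its spread, matching the separate SD and interaction
columns of the published results. The QC response is not utility-based: a
designated inattentive fraction (default 67/1203, the observed rate) picks
the dominated profile and everyone else the dominant one, which makes the
downstream filter count exact and keeps the screening mechanism out of the
likelihood.

What the generator does **not** emulate: quota-sampling mechanics,
item nonresponse and dropout, inattention on non-QC tasks, correlated taste
heterogeneity, and any latent constructs beyond the three modelled ones.
Passing recovery tests therefore validates the estimator under the model's
own assumptions; they say nothing about robustness to misspecification in
real survey data.

## Quality control and scale diagnostics

`apply_qc_filter()` excludes a respondent if and only if the QC choice is
the dominated profile; choosing the opt-out on the QC task retains the
respondent (the study describes exclusion only for the least favorable
option). `descriptives()` reproduces a counts-and-percentages table plus
per-scale means and SDs of respondent-level item averages.
`cronbach_alpha()`, `composite_reliability()` and
`average_variance_extracted()` implement

$$\alpha = \tfrac{k}{k-1}\Bigl(1 - \tfrac{\sum_i s_i^2}{s_T^2}\Bigr),\qquad
  CR = \tfrac{(\sum\lambda)^2}{(\sum\lambda)^2 + \sum(1-\lambda^2)},\qquad
  AVE = \tfrac{1}{k}\sum\lambda^2,$$

with standardized loadings obtained from the ordered-logit loadings as
$\lambda = \zeta/\sqrt{\zeta^2 + \pi^2/3}$ (the logistic measurement-error
variance).

## Joint estimation

`fit_hcm()` maximizes the simulated log-likelihood

$$\log L = \sum_n \log \frac{1}{R} \sum_{r=1}^{R}
  \Bigl[\prod_{t} P_{nt}(y_{nt} \mid \eta_r, \xi_r)\Bigr]
  \Bigl[\prod_{i} P(Y_{ni} \mid \eta_r)\Bigr],$$

a joint average over $R$ draws of the three structural disturbances and the
eight coefficient shocks, so the choice and measurement components are
estimated simultaneously and share the latent draws. Key numerical choices:

* **Draws.** Scrambled Halton sequences by default (`draw_config()`), 500
  per respondent, digit-permutation scrambling with the zero digit fixed,
  per-respondent contiguous blocks; MLHS and pseudo-random draws are
  available. Sign flips of any $\sigma_k$ leave the likelihood unchanged in
  distribution; at a fixed finite draw set the identity holds only up to
  simulation noise, and SDs are reported as absolute values.
* **Accumulation** is in log space per draw, so nondegenerate parameter
  values never produce `-Inf`; with all SDs, loadings and latent effects at
  zero the simulated value collapses to the closed-form conditional-logit
  (plus threshold-only measurement) likelihood exactly, which the tests
  assert at `1e-10`.
* **Gradient.** The score is computed analytically in compiled code
  (RcppArmadillo) alongside the likelihood — the practice of
  high-performance mixed-logit estimators — and is verified against central
  finite differences in the test suite. Per-respondent scores feed the
  robust covariance.
* **Thresholds** are estimated through a monotone reparameterization
  (first threshold free, increments on the log scale) and reported on the
  natural scale; starting values are quantile-matched to the observed
  cumulative indicator shares. Remaining starts: plain-MNL choice means and
  opt-out constant, 0.1 for SDs and all latent effects, loadings 1.
* **Optimization.** `nlminb` (quasi-Newton) with the analytic gradient,
  up to 1000 iterations by default; because PORT occasionally reports
  relative convergence while the gradient is still large, the fit restarts
  the optimizer (fresh curvature) up to five times. The `converged` flag
  requires the max-norm of the gradient to fall below `1e-6` relative to
  the log-likelihood magnitude.
* **Missing Likert responses** contribute nothing to the measurement
  product for that item.

`fit_mixed_logit()` is the same machinery with the latent component removed
— the main-effects heterogeneity check — and `fit_mnl()` the closed-form
conditional logit used for starting values and cross-checks (it matches
`survival::clogit` to `1e-4` in the tests). Robust standard errors are the
sandwich $H^{-1} B H^{-1}$, with $H$ the observed information obtained by
finite differences of the analytic gradient and $B$ the outer-product sum of
per-respondent scores; p-values are two-sided normal with significance
stars at 1/5/10 %. `wtp()` reports $-b_k/b_{\text{premium}}$ in RMB per
year with delta-method standard errors and refuses the ratio when the
premium coefficient is numerically zero.

The candidate interaction set crosses the seven attribute levels with
significant main-effects heterogeneity with nine variables (three latents,
six covariates), 63 terms; the default estimated specification carries the
21 published ones.

## Validation strategy and problem sizes

The test suite works at sizes chosen to keep the full run in minutes on one
CPU while leaving the checks sharp: moment checks of the generator at
$n = 10^5$ draws; degenerate-equivalence at 50 respondents; a
one-dimensional random-coefficient model against Gauss–Hermite quadrature
(60 nodes, agreement within $10^{-3}$); parameter recovery by simulating
from the reference parameter set at $n = 1000$ respondents and $R = 500$
draws and refitting — three replicates, every choice-mean estimate within
three Monte-Carlo standard errors of the truth, the MC SE estimated by the
information-based standard error (a replicate SD with two degrees of
freedom would be far noisier than the quantity it estimates); 100 seeded
coordinate-exchange runs
that must never end worse than their random start, plus exhaustive-search
equivalence on a toy; and exact reproduction of the study's screening
arithmetic (1203 completers, 67 dominated choosers, 1136 retained; 63
candidate interactions; the printed descriptive percentages).

## Known limitations

* The measurement thresholds and the exact supplementary likelihood of the
  original analysis are unavailable; the ordered-logit ICLV here is a
  documented reconstruction, and threshold-dependent quantities (scale
  means, opt-out share under latent shifts) differ from the published
  descriptive values by construction.
* Random coefficients are independent and normal; correlated or lognormal
  taste distributions, Bayesian estimation and WTP-space models are out of
  scope.
* Simulated maximum likelihood carries $O(1/R)$ bias; loadings far above 3
  on the logit scale remain mildly attenuated at $R = 500$.
* The published text reports 584 male respondents where its descriptive
  table codes 584 as female (51.4 %); the package follows the table's
  coding.
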