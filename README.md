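# hcmdce — hybrid choice analysis of inclusive health insurance preferences

`hcmdce` is an R package for stated-preference studies of complementary
inclusive ("Huimin"-type) health insurance: low-premium, high-deductible
commercial products that cover catastrophic health spending, usually with
some degree of government involvement. It implements the complete
quantitative workflow of such a study:

* **Experimental design** — D-efficient blocked discrete choice experiments
  by coordinate exchange, with dominance screening, near level balance,
  and a dominance-based quality-control (QC) task
  (`generate_design()`, `d_error()`, `make_qc_set()`).
* **Synthetic survey generation** — a first-class generator with the full
  statistical structure the analysis assumes (covariates, three latent
  constructs, eleven ordered-logit Likert indicators, panel choices with
  random coefficients and an opt-out), so every downstream stage is
  testable without the request-only survey data
  (`simulate_survey()`, `default_true_params()`).
* **Preprocessing** — the QC attentiveness filter, descriptive tables, and
  scale diagnostics: Cronbach's alpha, composite reliability, average
  variance extracted (`apply_qc_filter()`, `scale_diagnostics()`).
* **Estimation** — joint simulated maximum likelihood for the integrated
  choice and latent variable (ICLV / hybrid choice) model and the
  main-effects panel mixed logit, with scrambled Halton draws, an analytic
  score in compiled code, robust sandwich standard errors, and
  willingness-to-pay post-processing
  (`fit_hcm()`, `fit_mixed_logit()`, `robust_se()`, `wtp()`).
* **Reporting** — publication-style latent-variable and choice-model
  tables and a reproducible end-to-end pipeline
  (`render_tables()`, `run_pipeline()`), plus a thin command-line wrapper
  in `inst/cli/hcmdce.R`.

## The model

For respondent $n$, three latent constructs follow the sequential
structural recursion (disturbances standard normal)

$$\mathrm{HR}_n = \gamma_{HR}'z_n + \eta_1,\quad
  \mathrm{AW}_n = \gamma_{AW}'z_n + \lambda_{HR\to AW}\mathrm{HR}_n + \eta_2,\quad
  \mathrm{VAL}_n = \gamma_{VAL}'z_n + \lambda_{HR\to VAL}\mathrm{HR}_n
      + \lambda_{AW\to VAL}\mathrm{AW}_n + \eta_3,$$

measured by eleven 5-point Likert indicators through ordered logits with
loadings $\zeta_i$ and thresholds $\tau_{ik}$. Choice utilities over two
insurance profiles plus an opt-out are

$$V_{ntj} = \sum_k (b_k + \sigma_k \xi_{nk})\, x_{jk}
          + \sum_m \theta_m w_{nm} x_{j,k(m)},\qquad
  V_{nt,\mathrm{opt}} = \delta + \varphi'(\mathrm{HR},\mathrm{AW},\mathrm{VAL})_n,$$

with respondent-level normal random coefficients and latent- and
covariate-by-attribute interactions. All components are estimated
simultaneously by maximizing the simulated log-likelihood
$\sum_n \log R^{-1} \sum_r (\text{choice product}) \times
(\text{measurement product})$ over joint draws. Willingness to pay for a
non-premium attribute level is $-b_k / b_{\text{premium}}$ in RMB per year.

See `vignettes/hybrid-choice-methods.Rmd` for the full account of the
model, the numerical choices and the validation strategy.

## Worked example

```r
library(hcmdce)

design <- generate_design(huimin_attributes(), seed = 20230901, n_restarts = 3)
print(design)
survey <- simulate_survey(n = 1203, design, seed = 42)  # 67/1203 inattentive
qc     <- apply_qc_filter(survey)
cat("excluded:", qc$n_excluded, " retained:", length(qc$retained), "\n")
fit    <- fit_hcm(qc$dataset, draws = draw_config("halton", 200, seed = 7))
print(fit)
print(wtp(fit), digits = 4)
```

```
Choice design: 24 experimental sets in 4 blocks, 1 QC set(s)
D-error: 0.0477375
excluded: 67  retained: 1136
Hybrid choice model fit (joint latent + choice)
  respondents: 1136 | tasks: 6816 | draws: 200 halton
  log-likelihood: -22299.819 | converged: TRUE (max |grad| = 0.021 )
  choice means:
            premium government_moderate   government_strong          deductible
            -0.0062              0.7446              0.9408             -0.0056
      reimbursement  services_expanded1  services_expanded2  services_expanded3
             0.0419              0.5305              0.6573              0.8855
                level     wtp     se
1 government_moderate 120.009 22.217
2   government_strong 151.615 29.893
3          deductible  -0.905  3.091
4       reimbursement   6.756  1.345
5  services_expanded1  85.491 22.243
6  services_expanded2 105.927 22.392
7  services_expanded3 142.704 26.284
```

The QC filter drops exactly the simulated inattentive respondents (67 of
1203, leaving the study's 1136 valid cases). The fitted choice means sit
near the generating values (for example, premium −0.0062 against a true
−0.007 per RMB, strong government involvement 0.94 against 0.88) with the
hypothesized signs; the deductible mean, a weak effect, is within one
standard error of its small true value. The WTP table prices each
improvement in RMB of annual premium with delta-method standard errors:
here a strong government role is worth about 152 RMB per year and each
additional point of reimbursement rate about 6.8 RMB.

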