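# cfcount

Control-function estimation of the causal effect of a **binary endogenous
exposure** on a **count outcome**, by two-stage residual inclusion (2SRI),
with the full surrounding workflow of an applied survey analysis: variable
construction and filtering, probit first stage with average marginal effects,
instrument diagnostics, bootstrap inference, placebo falsification, subsample
heterogeneity runs, and a synthetic survey generator with known ground truth.

The motivating application is demographic: does adequate menstrual hygiene
management (MHM, a binary indicator built from three questionnaire items)
causally affect the fertility of ever-married women aged 15–49, measured as
children ever born (CEB)? MHM is endogenous — unobserved social norms drive
both hygiene practice and fertility — so household water/sanitation/hygiene
(WASH) availability serves as the excluded instrument. The same machinery
applies to any design with one endogenous binary treatment, a count outcome,
and factor-coded instruments.

## The model

Outcome and selection equations share a latent normal error:

```
CEB_i = x1_i' beta + gamma * MHM_i + e_i
MHM_i = 1[ x_i' alpha + eps_i >= 0 ],   eps_i ~ N(0, 1)
E(e_i | eps_i) = delta * eps_i
```

where `x_i = (x1_i, w_i)` adds the excluded WASH instruments `w_i` to the
exogenous controls `x1_i`. Estimation is the standard two-step procedure:

1. **Probit first stage** `Pr(MHM_i | x_i) = Phi(x_i' alpha)`, fitted by
   Newton maximum likelihood.
2. **Generalized residuals** (the probit score residual), with
   `mu(.) = phi(.)/Phi(.)` the inverse Mills ratio:

   ```
   m_i = MHM_i * mu(x_i' alpha) - (1 - MHM_i) * mu(-x_i' alpha)
   ```

3. **Poisson second stage** with log link,
   `E(CEB | x1, MHM, m) = exp(x1' beta + gamma MHM + delta m)`; the z-test on
   `delta` is the endogeneity test, and a pairs bootstrap re-running both
   stages per replicate accounts for the generated regressor. Percentage
   effects are reported as `(exp(b) - 1) * 100` (the incidence-rate-ratio
   transform). A negative-binomial (NB2, variance `mu + alpha mu^2`) second
   stage and an OLS placebo stage are provided for sensitivity and
   falsification.

Instrument diagnostics run on the linear 2SLS form of the same design:
Kleibergen–Paap rank LM (under-identification, df = L instruments),
Kleibergen–Paap rank Wald F and Cragg–Donald F against Stock–Yogo critical
values (weak instruments), and Hansen J (over-identification, df = L − 1).

## Worked example

Everything is exercisable without restricted microdata through the synthetic
generator, whose defaults emulate the survey conditions (n = 4,989 women,
five-category WASH shares near 2/24/9.5/42/23 percent, 5% exposure
missingness, endogeneity loading `delta = 0.3`, true exposure effect
`gamma = 0.05`):

```r
library(cfcount)

tab   <- simulate_survey(sim_config(), seed = 1)
prep  <- prepare_survey(strip_truth(tab))   # filters + probit imputation
roles <- default_roles()

fit   <- fit_cf_2sri(prep$data, roles, n_boot = 200, seed = 1)
naive <- fit_poisson(prep$data, roles)

tidy(fit)[, c("term", "estimate", "conf_low", "conf_high", "irr_percent")]
diagnose_instruments(prep$data, roles, cf_fit = fit)
```

Output (seed 1):

```
naive gamma: 0.479
       term estimate std_error conf_low conf_high irr_percent
1       mhm   0.0837    0.0834  -0.0798     0.247        8.73
2 gen_resid   0.2569    0.0517   0.1556     0.358       29.29

<iv_diagnostics> L = 4
  KP rk LM       308.364  df 4  p 0.0000
  KP rk Wald F    98.360  (Stock-Yogo 10% bias: 10.27)
  Cragg-Donald F  84.863
  Hansen J         2.228  df 3  p 0.5264
  endogeneity z    4.971  p 0.0000
```

Read: the naive Poisson coefficient on the exposure (0.479) is badly inflated
by selection on the shared latent error; the control-function estimate
(0.084, bootstrap CI covering the true 0.05) removes almost all of that bias,
and the significant generalized-residual term (z = 4.97) correctly flags the
exposure as endogenous. The instruments are strong (rank Wald F 98 against
the 10.27 critical value) and pass over-identification (Hansen J p = 0.53).
First-stage WASH marginal effects from `marginal_effects(fit$first_stage)`
span 25–56 probability points across categories. `run_placebo()` re-runs the
design against household-head age (no causal channel) and `run_subsample()`
refits on the rural and 15–29 cohorts; `run_analysis(run_config(...))`
drives the whole pipeline from a YAML config or an in-code configuration and
writes CSV/JSON reports.

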