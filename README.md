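# bayesidm

Bayesian illness–death multistate models for comparing surgery and
radiotherapy outcomes in localized prostate cancer — and, more generally,
for any three-state progression process (healthy → metastatic clinical
failure → death, plus healthy → death) observed under right censoring
with missing baseline covariates.

The package is aimed at biostatisticians analysing observational
treatment-comparison cohorts in which (a) several outcomes matter at once
(metastasis, death after metastasis, death from other causes), (b) events
are few relative to the confounders that must be adjusted for, and (c)
covariates are incompletely recorded.

## The model

Three proportional-hazards transition submodels with parametric baselines,

λ_k(t | x) = λ0_k(t) · exp(x'β_k),  k ∈ {1→2, 1→3, 2→3},

with Weibull λ0(t) = (α/b)(t/b)^(α−1) by default (piecewise-exponential
and exponential alternatives per transition).  The 2→3 transition is
semi-Markov with a **clock reset**: its hazard runs on time since entry
into the clinical-failure (CF) state, with the CF time (scaled, u/15)
included as a covariate.  Follow-up is administratively censored at 15
years.  Estimation is Metropolis-within-Gibbs MCMC with regularizing
normal priors — shrinkage on the standardized adjustment covariates is
what permits keeping every confounder in every submodel — and missing
covariates are redrawn every iteration by a chained-equations imputation
step embedded in the chain.  From a fit, individualized four-state
occupancy probabilities

P1 alive without prior CF · P2 alive after CF · P3 dead after CF · P4 dead without CF

are computed for any covariate profile under either treatment, which is
the computational core of an individualized treatment-choice calculator
(P1 is metastasis-free survival; P1+P2 is overall survival).

Because the motivating institutional cohort is not publicly deposited, the
package ships a first-class synthetic-cohort generator that reproduces the
cohort's structure (marginals, confounded treatment assignment,
published event rates, censoring, missingness) from the published
descriptive statistics; all simulation studies and tests run against it.
See the methods vignette (`vignettes/illness-death-methods.Rmd`) for the
full account.

## Worked example

```r
library(bayesidm)

cfg    <- synthetic_config(n = 1500, seed = 42)   # emulated cohort structure
gen    <- generate_cohort(cfg)
cohort <- apply_missingness(gen$cohort, cfg)       # published missingness rates

fit <- idm_bayes(cohort, spec = cfg$spec,
                 control = idm_control(iters = 4000, burn_in = 1500, thin = 2),
                 seed = 7)
print(fit)
#> Bayesian illness-death model fit
#>   1500 patients; events: CF 61, death w/o CF 111, death after CF 33
#>   1250 retained draws (4000 iterations, burn-in 1500, thin 2), seed 7
#>   acceptance: median 0.33 (range 0.28-0.37); min ESS 24; max split-Rhat 1.027
#>   imputed fields: gland_volume (511), psa (3), cci (335), gleason (6), pni (26), ct (3), race (311)

tab <- summary(fit)                                # posterior HR table
tab[tab$term == "treatment_rt", ]
#>  transition         term  arm   hr lower upper ess
#>         t12 treatment_rt both 1.71  0.80  3.04 334
#>         t13 treatment_rt both 1.84  1.13  2.74 180
#>         t23 treatment_rt both 1.55  0.56  3.46 262

patient <- data.frame(age = 65, psa = 30, gland_volume = 40, cci = "0",
                      gleason = "9/10", pni = 1, ct = "2", race = "White",
                      tx_year = "2007-2013", treatment = "surgery")
predict(fit, patient, treatment = "both", horizons = 10)
#> Predicted state occupancy: surgery vs radiotherapy
#>   10-y alive & disease-free: surgery 78%, radiotherapy 66%
#>   10-y overall survival:     surgery 80%, radiotherapy 68%
```

The hazard ratios are per-transition: here (synthetic data, n = 1500, wide
intervals) radiotherapy is associated with HR 1.84 (95% CrI 1.13–2.74) for
death from other causes — driven by the generator's confounding plus its
true effect — while the CF and post-CF effects are not distinguishable
from 1.  The prediction block turns the same fit into absolute 10-year
probabilities for one hypothetical patient under each treatment.
`plot(fit)` draws a forest plot, `plot(predict(fit, patient, "surgery"))`
a stacked-area occupancy plot, and `posterior_occupancy()` adds pointwise
95% credible bands.  `run_pipeline()` chains
simulate → fit → summarize → predict and writes all artifacts (summary
tables, forest CSVs, occupancy curves, diagnostics, manifest with hashes)
to a directory.

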