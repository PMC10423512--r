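# drcohort

Doubly robust risk-ratio analysis of systolic blood pressure (SBP)
categories in longitudinal electronic health records (EHR), with COPD
cohorts as the motivating setting.

## The problem

Observational cohorts of multimorbid patients often show a *J-shaped*
association between SBP and cardiovascular risk: crude risk looks
elevated below the reference band as well as above it. A standard
explanation is confounding by latent multimorbidity — frail patients
have lower blood pressure (reverse causality) *and* higher risk — which
hand-picked covariate adjustment does not remove. `drcohort` implements
the analysis pipeline that confronts this: a sequence encoder over each
patient's pre-baseline diagnosis/medication token stream with two heads,

* a 6-way exposure **propensity** head `g_k(x) = P(E = k | history)`, and
* per-category **outcome** heads `Q_k(x) = P(Y = 1 | history, E = k)`,

combined into augmented inverse-probability-weighted (AIPW) marginal
risks

```
psi_k = (1/n) * sum_i [ 1{E_i = k} (Y_i - Q_k(X_i)) / max(g_k(X_i), eps)
                        + Q_k(X_i) ],        RR_k = psi_k / psi_ref
```

which are consistent when *either* head is correct (double robustness).
Exposure categories are the mean of cleaned SBP readings (50–300 mm Hg)
over the 12 months after the first eligible reading, binned as `<120`,
`120–129` (reference), `130–139`, `140–149`, `150–159`, `≥160`;
outcomes are a composite of ischaemic heart disease, heart failure,
stroke and cardiovascular death between 1 and 6 years after baseline.

The package also provides the conventional arm for comparison
(logistic regression with base or expanded covariate sets,
chained-equation multiple imputation, direct standardisation, Rubin
pooling), a synthetic EHR generator with a latent multimorbidity
confounder and a Monte-Carlo oracle for the true marginal risk ratios,
cohort construction with a selection flowchart, five sensitivity
analyses, descriptives, and forest tables.

## Worked example

```r
library(drcohort)

# 1. Simulate a confounded null cohort: true RR = 1 in every category,
#    but multimorbidity (latent U) lowers SBP and raises risk.
cfg <- sim_config(n_patients = 8000, seed = 7)
sim <- simulate_ehr(cfg)
print(sim$truth)
#> Ground-truth marginal risks (Monte-Carlo oracle, n_draws = 2e+05 )
#>  category    psi rr rr_mc_se
#>      <120 0.2843  1        0
#>   120-129 0.2843  1        0
#>   ...                           (all six RR = 1 under the null)

# 2. Build the analysable cohort.
built <- build_cohort(sim, cfg$run)
built$flowchart
#>                           step    n
#> 1                     patients 8000
#> 2  sbp_in_window_age_in_bounds 8000
#> 3             copd_at_baseline 8000
#> 4 no_event_or_exit_in_exposure 7601

# 3. Fit the doubly robust sequence model.
fit <- drseq(built$cohort, sim$events, encoder_config(seed = 1))
print(fit)
#> Doubly robust sequence-model risk ratios
#>   n = 7601  events = 2237  outcome: outcome_primary
#>
#>     analysis category events/n         RR (95% CI)
#>  dr_sequence     <120  253/697 1.17 (1.03 to 1.31)
#>  dr_sequence  120-129 334/1079    1.00 (reference)
#>  dr_sequence  130-139 513/1670 1.00 (0.89 to 1.13)
#>  dr_sequence  140-149 463/1673 0.88 (0.78 to 0.99)
#>  dr_sequence  150-159 386/1394 0.95 (0.83 to 1.09)
#>  dr_sequence    >=160 288/1088 0.94 (0.81 to 1.07)
round(fit$crude_rr, 2)
#> [1] 1.17 1.00 0.99 0.89 0.89 0.86

# 4. Conventional arm on the same cohort (imputation + standardisation).
lr <- lr_rr(built$cohort, predictors = "base",
            spec = imputation_spec(m = 5, seed = 2))
forest_table(list(fit$rr, lr))
```

The crude ratio for `<120` sits above 1 while the oracle truth is 1 —
the confounding artefact. At this small size (about 3 800 patients per
cross-fitting fold) the encoder has too little material to undo it and
the doubly robust estimate still shows the inflation with a CI
excluding 1; the packaged verification runs at n near 20 000, where the
null is recovered (all six estimates inside [0.85, 1.18] and the `<120`
estimate strictly closer to 1 than the crude one). Confounding-removal
capacity grows with cohort size — exactly the regime the method is
meant for.

A command-line pipeline (`simulate`, `build-cohort`, `estimate-dl`,
`estimate-lr`, `sensitivity`, `report`) is available through
`run_cli()` or the wrapper in `inst/cli/drcohort.R`.

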