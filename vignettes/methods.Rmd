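---
title: "Doubly robust risk-ratio estimation for blood-pressure categories in longitudinal health records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly robust risk-ratio estimation for blood-pressure categories in longitudinal health records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

In observational cohorts of patients with complex disease — chronic
obstructive pulmonary disease (COPD) is the motivating setting — the
association between systolic blood pressure (SBP) and cardiovascular risk
often appears J-shaped: risk seems elevated both above *and below* an
apparently optimal pressure. A leading explanation is confounding by
latent multimorbidity: frail, multimorbid patients tend to have *lower*
blood pressure (reverse causality) and *higher* cardiovascular risk, so
the lowest exposure category accumulates the sickest patients and its
crude risk is inflated. Conventional regression adjusts only for
hand-picked covariates and can leave much of this latent confounding in
place; a sequence model over the patient's full pre-baseline diagnosis
and medication stream can absorb far more of it, and combining its two
heads (outcome and propensity) doubly robustly yields marginal risk
ratios per SBP category.

`drcohort` implements this pipeline end to end at desk scale: a
synthetic EHR generator with known causal ground truth, a cohort builder,
the doubly robust sequence estimator `drseq()`, a conventional
logistic-regression comparator with chained-equation multiple imputation
and direct standardisation, and the sensitivity/descriptive reporting
around them.

## Study design encoded in `run_config()`

* Index date (baseline): a patient's first valid SBP reading between
  1990-01-01 and 2009-12-31, at an age of 55–90 years (inclusive at both
  ends — the source design does not state the boundary convention, so we
  fix the inclusive one and expose it in the configuration).
* Exposure: the arithmetic mean of cleaned SBP readings (values outside
  [50, 300] mm Hg discarded; the printed rule excludes "<50" and ">300",
  so the bounds themselves are retained) in the 365 days from baseline,
  binned into `<120`, `120–129` (reference), `130–139`, `140–149`,
  `150–159`, `≥160` with half-open integer edges, matching the printed
  labels for integer-valued means. Same-day readings count once, as
  their mean.
* Outcomes: a composite of ischaemic heart disease, heart failure,
  stroke and cardiovascular death (plus the components), ascertained
  from any source in the window `[baseline + 365 d, baseline + 2190 d)`
  — i.e. events between 1 and 6 years after baseline, keeping the
  outcome window disjoint from the exposure window. Patients with a
  qualifying event or registration exit inside the exposure period are
  excluded.
* All window arithmetic is in whole days with 12 months = 365 days,
  5 years = 1825 days; this keeps every windowing test exact.
* Covariates for the conventional arm (BMI, total cholesterol,
  triglycerides, LDL) are averages of measurements in the 36 months
  strictly *before* baseline. Whether the index day itself should count
  is not specified in the source design; we take strictly-before and
  expose the look-back length in the configuration.

The selection flowchart records, in order: all patients; ≥ 1 valid SBP
reading in the date window with age in bounds (this step *defines* the
baseline); COPD code on or before baseline; no event or exit during the
exposure period. Baseline-anchored predicates cannot be evaluated before
a baseline exists, which is why the SBP step comes first.

## The synthetic cohort generator

`simulate_ehr()` emulates the statistical structure that makes this
analysis hard, not the surface of any particular database. One latent
standard-normal multimorbidity score $U$ per patient drives everything:

* **Blood pressure.** Underlying SBP is
  $140 + 8\,\mathrm{age}_z - \gamma\,(\mathrm{softplus}(U) - 0.806) +
  \varepsilon$, with $\gamma = 12$ mm Hg, person-level spread 12 mm Hg,
  and repeated readings with 10 mm Hg measurement noise (Poisson mean 4
  readings in the exposure window). The frailty link is *one-sided*
  (softplus): multimorbidity drags pressure down — the reverse-causality
  mechanism — while good health does not push it up. This concentrates
  the confounding artefact in the low categories, where the J-shape
  lives, and matches the moderate disease gradients observed across the
  upper categories of real COPD cohorts. With a symmetric (linear) link
  the latent-score gradient accumulated between the reference and the
  top category is so large that *no* adjuster limited to
  history-derived information can recover the null there; the one-sided
  link is both the more faithful mechanism and the one that makes the
  estimand identifiable from the record stream.
* **Outcome.** Binary cardiovascular outcome with log-link risk
  $\min\{0.95,\; 0.25\,\exp(\beta_{k} + 0.4\,U + 0.15\,\mathrm{age}_z)\}$
  where $\beta_k$ is the true log conditional risk ratio of the assigned
  SBP category (reference entry 0). The 0.25 reference risk matches the
  overall crude event proportion of large published COPD cohorts
  (roughly 28%). Because the exposure is *set* rather than conditioned
  on, the marginal (standardised) truth still requires integrating over
  $(U, \mathrm{age})$; `oracle_marginal_rr()` does this by Monte Carlo
  (default $2\times10^5$ draws) and reports Monte-Carlo standard errors.
  In the degenerate no-confounding, no-age limit the oracle reduces to
  the closed form $\psi_k = p_0 e^{\beta_k}$, which the tests verify.
* **History stream.** Pre-baseline diagnosis/medication tokens arrive at
  10/year scaled by $e^{0.5 U}$ over a 2–10-year registration history,
  and each token is a chronic-disease code (IHD, AF, CKD, diabetes, RA,
  severe mental illness) with probability
  $\mathrm{logit}^{-1}(\mathrm{logit}(0.15) + U)$. Token *rate* and
  chronic *share* are therefore the two channels through which the
  latent score is visible to any adjuster; their loadings were fixed, at
  design time, so that roughly 90% of the variance of $U$ is
  recoverable from a full history — enough that doubly robust
  adjustment of the null is possible, while still leaving visible crude
  confounding. Antihypertensive use increases with underlying SBP
  (logit slope 0.004/mm Hg around 33% at 140 mm Hg), reproducing the
  rising antihypertensive gradient of real cohorts and exercising the
  no-antihypertensive sensitivity analysis; beta-blockers, LABA and
  inhaled corticosteroids are emitted at fixed realistic rates.
* **Missingness.** BMI, TC, TG, LDL and smoking are masked at the
  published rates (56.3%, 71.7%, 80.7%, 85.6%, 24.4%) under MCAR or MAR
  (logit slope 0.5 per 10 years of age, intercept calibrated to the
  marginal rate).
* **Early exits.** 5% of patients have a qualifying event or a
  registration exit inside the exposure period, exercising the
  early-exclusion path. Exits *after* the exposure period default to
  zero so that every analysed patient carries the full 6-year outcome
  window and the Monte-Carlo oracle is exact under the binary-risk
  design; a `followup_exit_rate` parameter exists for experimentation,
  with exits counted as non-events (the binary-risk design has no
  censoring model — the same limitation the source design states for
  itself).

What the generator deliberately does **not** emulate: real code
vocabularies and phenotyping, practice-level clustering, time-varying
exposure, informative censoring, and calendar-time trends. Tests passing
on this generator show that the estimator recovers known truths under
the stated confounding structure; they do not certify performance on
real EHR data.

## The doubly robust sequence estimator

`drseq()` tokenises each patient's pre-baseline record (static tokens
for sex, smoking, 5-year age band and registration-span band, followed
by dated event tokens, newest 256 kept) and trains a shared encoder:
token + age-band embeddings, multi-head attention pooling (2 heads, a
learned query per head), a patient-level log-history-length feature, and
2 dense ReLU layers of width 64. Three heads share the trunk:

* a 6-way softmax **propensity** head $\hat g_k(x)$,
* per-category sigmoid **outcome** heads $\hat Q_k(x)$,
* a **masked-token** head (15% of history tokens replaced by `[MASK]`,
  their identities predicted from the pooled representation; weight
  0.1). With pooling there is no per-position output, so the masked
  prediction is patient-level — a deliberate simplification of the
  usual per-position objective that still regularises the embeddings.

Training is hand-written reverse-mode differentiation with Adam (10
epochs, batch 256, peak learning rate 2e-3 with cosine decay to 10%,
decoupled weight decay 0.01 on attention/dense/head weights). The
gradient code is validated against central finite differences in the
test suite. Five epochs of constant-rate Adam — a plausible first
choice — measurably underfits both heads in this implementation, which
is why the defaults are 10 epochs with decay; outcome-head loss is
upweighted (×2) because the standardisation step leans hardest on
$\hat Q_k$.

The heads are combined by AIPW:
$$\hat\psi_k = \frac1n \sum_i \Big[ \frac{\mathbf 1\{E_i = k\}\,(Y_i -
\hat Q_k(X_i))}{\max(\hat g_k(X_i), \epsilon)} + \hat Q_k(X_i) \Big],
\qquad \widehat{RR}_k = \hat\psi_k / \hat\psi_{\mathrm{ref}},$$
with positivity guard $\epsilon$ and percentile bootstrap CIs obtained
by resampling patients and re-averaging the influence terms (200
replicates by default; a full-refit bootstrap would multiply cost by the
replicate count for little change in these bands). The reference row is
reported as RR 1 with no CI. The estimate is consistent when either
head is correct; the tests exercise both oracle substitutions.

Two implementation choices matter in practice and were adopted after
observing their effects on synthetic data:

* **Cross-fitting** (default): the cohort is split in two; each half is
  scored by an encoder trained on the other half. Because the
  propensity head shares its trunk with the outcome head, a
  single-sample fit makes $\hat g$ correlated with the outcome
  residuals and visibly biases the AIPW combination even when the true
  $Q$ is substituted; cross-fitting removes this term at no extra cost
  (two fits on half the data).
* **One-step AIPW** rather than an iterated TMLE fluctuation: the same
  double-robustness guarantee, fully specified, and the fluctuation
  details are not pinned down by the source design.

## The conventional comparator

`lr_rr()` fits maximum-likelihood logistic regression of the outcome on
the 6-level exposure (reference 120–129) plus either the *base*
covariate set (sex, age, BMI, smoking status, beta-blocker, LABA,
inhaled corticosteroid) or the *expanded* set (base + TG, LDL, TC,
atrial fibrillation, rheumatoid arthritis, severe mental illness,
chronic kidney disease, diabetes). Age enters linearly; smoking as
dummies against never (the covariate lists name variables, not codings).
Missing covariates are multiply imputed by chained equations
(`impute_chained()`, 15 imputations by default): Bayesian linear
regression draws for the continuous variables, a multinomial logistic
model fitted on a bootstrap resample of observed rows for smoking, 5
cycles. Marginal risks come from direct standardisation (predict every
patient at every exposure level, average, take ratios); per-imputation
CIs from a 200-replicate patient bootstrap; imputations pooled on the
log-RR scale by Rubin's rules with the standard degrees-of-freedom
correction. The crude (exposure-only) standardised RR is algebraically
the ratio of raw event proportions, an identity the tests check to
1e-10.

## Numerical and degenerate-input conventions

* Quantiles everywhere are type-7 (linear interpolation), so
  descriptives are deterministic across implementations.
* Same-day SBP readings collapse to one value; categories use half-open
  integer edges; means of exactly 160 fall in `≥160`.
* Empty exposure categories abort the encoder fit with the category
  named; an empty cohort after selection aborts with advice to review
  the configuration; a 100%-missing variable aborts imputation.
* All randomness flows from configuration seeds: identical
  configurations reproduce identical tables, fits and intervals.

## Problem sizes used by the automated checks

The packaged checks run at sizes chosen for a single desktop core: null
recovery and the J-shape contrast on one simulated cohort of ~20,500
analysable patients; double robustness by oracle-head substitution on
the same cohort; monotone recovery on 10 replicates of ~9,500 patients;
imputation coverage on 50 replicates of 2,500 patients with 5
imputations and a 60-replicate bootstrap per completed dataset (the
analysis default remains 15 imputations and 200 bootstrap replicates).
The J-shape demonstrations turn the confounding dial up
(`confounding_sbp = 16`, `confounding_outcome = 0.7`) relative to the
default study conditions, as they are explicitly demonstrations of the
artefact's magnitude growing with confounding.

## Known limitations

* Binary-risk design: no time-to-event modelling, so post-exposure
  censoring would bias risks toward zero if enabled; the default
  generator therefore completes follow-up for analysed patients.
* The encoder is desk-scale; it adjusts what is recoverable from the
  token stream at these sizes and no more. Residual confounding of a
  few percent on the log scale at the extreme categories is expected
  and visible in the tests' tolerance bands.
* The masked-token objective is patient-level, not per-position.
* Imputation treats rows as exchangeable; no practice-level structure.
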