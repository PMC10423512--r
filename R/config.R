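#' Analysis run configuration
#'
#' Collects the design constants of the cohort analysis: the eligible
#' index-date window, age bounds, exposure and follow-up window lengths (in
#' whole days), SBP category edges and the valid measurement range.
#'
#' Defaults encode the study design: index dates 1990--2009, ages 55--90
#' inclusive at baseline, a 365-day exposure period over which SBP readings
#' are averaged, follow-up starting 365 days after baseline and spanning
#' 1825 days (events between 1 and 6 years after baseline), and SBP
#' readings outside [50, 300] mm Hg discarded.
#'
#' @param date_window length-2 character/Date: first and last eligible
#'   index date.
#' @param age_bounds inclusive age range at baseline, in years.
#' @param exposure_days length of the exposure averaging window (days).
#' @param followup_start_days days after baseline at which follow-up
#'   starts; must be >= `exposure_days`.
#' @param followup_span_days length of the outcome window (days).
#' @param category_edges strictly increasing SBP cut points.
#' @param sbp_valid_range inclusive range of plausible SBP values (mm Hg).
#' @param covariate_lookback_days window before baseline over which BMI and
#'   lipid measurements are averaged (strictly pre-baseline).
#' @param seed integer seed governing all randomness downstream.
#' @return an object of class `run_config` (a validated list).
#' @export
run_config <- function(date_window = c("1990-01-01", "2009-12-31"),
                       age_bounds = c(55L, 90L),
                       exposure_days = 365L,
                       followup_start_days = 365L,
                       followup_span_days = 1825L,
                       category_edges = c(120, 130, 140, 150, 160),
                       sbp_valid_range = c(50, 300),
                       covariate_lookback_days = 1095L,
                       seed = 1L) {
  date_window <- as.Date(date_window)
  .assert(length(date_window) == 2L && !anyNA(date_window) &&
            date_window[1] <= date_window[2],
          "date_window must be two ordered dates")
  .assert(length(age_bounds) == 2L && age_bounds[1] <= age_bounds[2],
          "age_bounds must be an ordered pair")
  .assert(.is_count(exposure_days), "exposure_days must be a positive integer")
  .assert(.is_count(followup_start_days) &&
            followup_start_days >= exposure_days,
          "followup_start_days must be >= exposure_days")
  .assert(.is_count(followup_span_days),
          "followup_span_days must be a positive integer")
  .assert(all(diff(category_edges) > 0),
          "category_edges must be strictly increasing")
  .assert(sbp_valid_range[1] < sbp_valid_range[2],
          "sbp_valid_range must be ordered")
  structure(list(
    date_window = date_window,
    age_bounds = as.integer(age_bounds),
    exposure_days = as.integer(exposure_days),
    followup_start_days = as.integer(followup_start_days),
    followup_span_days = as.integer(followup_span_days),
    category_edges = category_edges,
    sbp_valid_range = sbp_valid_range,
    covariate_lookback_days = as.integer(covariate_lookback_days),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Sequence-encoder and estimator configuration
#'
#' Hyperparameters of the doubly robust sequence model: a shared encoder
#' (token + age embeddings, multi-head attention pooling, dense layers)
#' with a 6-way propensity head, per-category outcome heads, and a
#' masked-token auxiliary head. Defaults are sized for desk-scale runs:
#' 2 layers of width 64 with 2 attention heads, sequences truncated to the
#' newest 256 tokens, 5 training epochs.
#'
#' @param max_sequence_length maximum tokens per patient (oldest dropped).
#' @param embedding_width embedding and hidden width.
#' @param n_layers number of dense layers after pooling.
#' @param n_attention_heads number of attention-pooling heads.
#' @param mask_fraction fraction of history tokens masked for the
#'   auxiliary masked-token task, in (0,1).
#' @param mask_weight weight of the masked-token loss.
#' @param outcome_weight weight of the outcome-head loss relative to the
#'   propensity loss (the standardisation step leans on the outcome
#'   head, so it is upweighted by default).
#' @param epochs,batch_size,learning_rate Adam training schedule.
#' @param weight_decay decoupled weight decay applied to attention, dense
#'   and head weight matrices (not embeddings or biases); stabilises the
#'   per-category outcome readouts.
#' @param propensity_clip positivity guard: estimated propensities are
#'   truncated below at this value in the AIPW combination.
#' @param bootstrap_reps nonparametric bootstrap replicates for the 95% CI
#'   (patients resampled, influence terms re-averaged).
#' @param seed integer seed for initialisation, batching and masking.
#' @return an object of class `encoder_config`.
#' @export
encoder_config <- function(max_sequence_length = 256L,
                           embedding_width = 64L,
                           n_layers = 2L,
                           n_attention_heads = 2L,
                           mask_fraction = 0.15,
                           mask_weight = 0.1,
                           outcome_weight = 2,
                           epochs = 10L,
                           batch_size = 256L,
                           learning_rate = 2e-3,
                           weight_decay = 0.01,
                           propensity_clip = 0.05,
                           bootstrap_reps = 200L,
                           seed = 1L) {
  .assert(propensity_clip > 0 && propensity_clip < 0.5,
          "propensity_clip must lie in (0, 0.5)")
  .assert(mask_fraction > 0 && mask_fraction < 1,
          "mask_fraction must lie in (0, 1)")
  for (nm in c("max_sequence_length", "embedding_width", "n_layers",
               "n_attention_heads", "epochs", "batch_size"))
    .assert(.is_count(get(nm)), "%s must be a positive integer", nm)
  .assert(learning_rate > 0, "learning_rate must be positive")
  structure(list(
    max_sequence_length = as.integer(max_sequence_length),
    embedding_width = as.integer(embedding_width),
    n_layers = as.integer(n_layers),
    n_attention_heads = as.integer(n_attention_heads),
    mask_fraction = mask_fraction,
    mask_weight = mask_weight,
    outcome_weight = outcome_weight,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    weight_decay = weight_decay,
    propensity_clip = propensity_clip,
    bootstrap_reps = as.integer(bootstrap_reps),
    seed = as.integer(seed)
  ), class = "encoder_config")
}

#' Synthetic cohort generator configuration
#'
#' Parameters of the synthetic EHR generator. A standard-normal latent
#' multimorbidity score U drives both blood pressure (downwards, through
#' `confounding_sbp`, mm Hg per SD of U) and cardiovascular risk (upwards,
#' through `confounding_outcome`, log-risk per SD of U), reproducing the
#' confounding structure in which poor underlying health concentrates at
#' low SBP. True per-category conditional risk ratios are set directly on
#' the log scale via `true_log_rr` (reference entry must be 0); marginal
#' ground truths are obtained with [oracle_marginal_rr()].
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer seed; identical configs give identical output.
#' @param confounding_sbp effect of U on underlying SBP (mm Hg per SD;
#'   entered negatively, so larger values push multimorbid patients low).
#' @param confounding_outcome effect of U on log outcome risk.
#' @param true_log_rr numeric length-6 vector of per-category log
#'   conditional risk ratios; entry `reference` must equal 0.
#' @param reference index of the reference category (2 = 120-129 mm Hg).
#' @param baseline_risk reference-category risk for an average patient.
#' @param age_log_risk log-risk slope per 10 years of age.
#' @param risk_cap upper clip for per-patient event probability.
#' @param sbp_person_sd between-person SD of underlying SBP beyond age and
#'   U (mm Hg).
#' @param sbp_noise_sd within-person measurement noise SD (mm Hg).
#' @param measurements_per_patient mean number of SBP readings in the
#'   exposure window (Poisson, minimum 1).
#' @param vocab_size number of filler diagnosis codes in the vocabulary
#'   (chronic-disease and medication codes are reserved on top).
#' @param tokens_per_year mean clinical events per year for U = 0.
#' @param token_rate_loading log-rate slope of event intensity on U.
#' @param chronic_share probability an event is a chronic-disease code at
#'   U = 0.
#' @param chronic_loading logit slope of the chronic-code share on U.
#' @param history_years range of pre-baseline registration length (years).
#' @param missing_rates named rates for `bmi`, `smoking`, `tc`, `tg`,
#'   `ldl`; defaults are the published cohort's missingness levels.
#' @param missing_mechanism `"MCAR"` or `"MAR"` (missingness depending on
#'   age through a logit model calibrated to the marginal rate).
#' @param antihypertensive_base probability of baseline antihypertensive
#'   use at SBP 140 mm Hg.
#' @param antihypertensive_slope logit slope of antihypertensive use per
#'   mm Hg of underlying SBP.
#' @param early_exit_rate probability of an exposure-period event or
#'   deregistration (these patients exercise the early-exclusion path).
#' @param followup_exit_rate probability of deregistration during
#'   follow-up; kept at 0 by default so that binary outcomes are fully
#'   observed and the oracle truth is exact.
#' @param run run_config giving windows, edges and age bounds.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       seed = 1L,
                       confounding_sbp = 12,
                       confounding_outcome = 0.4,
                       true_log_rr = rep(0, 6),
                       reference = 2L,
                       baseline_risk = 0.25,
                       age_log_risk = 0.15,
                       risk_cap = 0.95,
                       sbp_person_sd = 12,
                       sbp_noise_sd = 10,
                       measurements_per_patient = 4,
                       vocab_size = 60L,
                       tokens_per_year = 10,
                       token_rate_loading = 0.5,
                       chronic_share = 0.15,
                       chronic_loading = 1,
                       history_years = c(2, 10),
                       missing_rates = c(bmi = 0.563, smoking = 0.244,
                                         tc = 0.717, tg = 0.807,
                                         ldl = 0.856),
                       missing_mechanism = c("MCAR", "MAR"),
                       antihypertensive_base = 0.33,
                       antihypertensive_slope = 0.004,
                       early_exit_rate = 0.05,
                       followup_exit_rate = 0,
                       run = run_config(seed = seed)) {
  missing_mechanism <- match.arg(missing_mechanism)
  .assert(.is_count(n_patients), "n_patients must be a positive integer")
  .assert(length(true_log_rr) == length(run$category_edges) + 1L,
          "true_log_rr must have one entry per category")
  .assert(true_log_rr[reference] == 0,
          "true_log_rr must be 0 at the reference category")
  .assert(baseline_risk > 0 && baseline_risk < 1,
          "baseline_risk must lie in (0,1)")
  .assert(confounding_sbp >= 0, "confounding_sbp must be >= 0")
  .assert(all(missing_rates >= 0 & missing_rates <= 1),
          "missing_rates must lie in [0,1]")
  .assert(all(c("bmi", "smoking", "tc", "tg", "ldl") %in%
                names(missing_rates)),
          "missing_rates must name bmi, smoking, tc, tg, ldl")
  .assert(early_exit_rate >= 0 && early_exit_rate < 1,
          "early_exit_rate must lie in [0,1)")
  structure(list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    confounding_sbp = confounding_sbp,
    confounding_outcome = confounding_outcome,
    true_log_rr = true_log_rr, reference = as.integer(reference),
    baseline_risk = baseline_risk, age_log_risk = age_log_risk,
    risk_cap = risk_cap, sbp_person_sd = sbp_person_sd,
    sbp_noise_sd = sbp_noise_sd,
    measurements_per_patient = measurements_per_patient,
    vocab_size = as.integer(vocab_size),
    tokens_per_year = tokens_per_year,
    token_rate_loading = token_rate_loading,
    chronic_share = chronic_share, chronic_loading = chronic_loading,
    history_years = history_years, missing_rates = missing_rates,
    missing_mechanism = missing_mechanism,
    antihypertensive_base = antihypertensive_base,
    antihypertensive_slope = antihypertensive_slope,
    early_exit_rate = early_exit_rate,
    followup_exit_rate = followup_exit_rate,
    run = run
  ), class = "sim_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("Cohort run configuration\n")
  cat("  index dates:", format(x$date_window[1]), "to",
      format(x$date_window[2]), "\n")
  cat("  ages:", x$age_bounds[1], "-", x$age_bounds[2],
      " exposure:", x$exposure_days, "d",
      " follow-up: [", x$followup_start_days, ",",
      x$followup_start_days + x$followup_span_days, ") d\n")
  cat("  categories:", paste(.sbp_levels(x$category_edges), collapse = ", "),
      "\n")
  invisible(x)
}
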