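# Synthetic longitudinal EHR generator. A latent multimorbidity score U
# links low SBP to high cardiovascular risk, so that crude per-category
# risks show a J-shape even when the true category effects are null. The
# generator also produces the ground-truth marginal risks via a
# Monte-Carlo oracle, which the estimators are judged against.

.CHRONIC_CODES <- c("IHD", "AF", "CKD", "DIABETES", "RA", "SMI")
.OUTCOME_CODES <- c("IHD", "HF", "STROKE", "CVDEATH")

.age_z <- function(age) (age - 70) / 10

.softplus <- function(x) log1p(exp(pmin(x, 30))) + pmax(x - 30, 0)
.SOFTPLUS_MEAN <- 0.80645  # E[softplus(Z)] for Z ~ N(0,1)


# per-patient conditional event probability under the log-link model
.risk <- function(cfg, k, u, age) {
  pmin(cfg$risk_cap,
       cfg$baseline_risk *
         exp(cfg$true_log_rr[k] + cfg$confounding_outcome * u +
               cfg$age_log_risk * .age_z(age)))
}

#' Monte-Carlo oracle for marginal risks and risk ratios
#'
#' Computes, for each SBP category k, the standardised (marginal) risk
#' `psi_k = E[P(Y=1 | category set to k, U, age)]` by Monte-Carlo
#' integration over the latent score and age distribution (the exposure is
#' *set*, not conditioned on, so `psi_k` is the causal quantity that direct
#' standardisation and the doubly robust estimator target), together with
#' `RR_k = psi_k / psi_ref` and Monte-Carlo standard errors.
#'
#' @param config a [sim_config()].
#' @param n_draws Monte-Carlo draws (>= 1e5 for acceptance use).
#' @param seed seed for the oracle draws (defaults to `config$seed + 1`).
#' @return object of class `sim_truth`: list with `categories`, `psi`,
#'   `rr`, `psi_se`, `rr_se`, `reference`, `n_draws`.
#' @export
oracle_marginal_rr <- function(config, n_draws = 2e5,
                               seed = config$seed + 1L) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  k6 <- length(config$true_log_rr)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  u <- stats::rnorm(n_draws)
  age <- stats::runif(n_draws, config$run$age_bounds[1],
                      config$run$age_bounds[2])
  p <- vapply(seq_len(k6), function(k) .risk(config, k, u, age),
              numeric(n_draws))
  psi <- colMeans(p)
  psi_se <- apply(p, 2, stats::sd) / sqrt(n_draws)
  ref <- config$reference
  rr <- psi / psi[ref]
  # influence-function SE of the ratio (draws shared across categories)
  rr_se <- vapply(seq_len(k6), function(k) {
    f <- (p[, k] - rr[k] * p[, ref]) / psi[ref]
    stats::sd(f) / sqrt(n_draws)
  }, 0)
  rr_se[ref] <- 0
  structure(list(categories = .sbp_levels(config$run$category_edges),
                 psi = psi, rr = rr, psi_se = psi_se, rr_se = rr_se,
                 reference = ref, n_draws = n_draws),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Ground-truth marginal risks (Monte-Carlo oracle, n_draws =",
      format(x$n_draws, big.mark = ","), ")\n")
  print(data.frame(category = x$categories,
                   psi = signif(x$psi, 4), rr = signif(x$rr, 4),
                   rr_mc_se = signif(x$rr_se, 3)), row.names = FALSE)
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' Mask covariates at configured missingness rates
#'
#' Independently sets each covariate to missing at its configured rate.
#' Under `"MCAR"` the mask is independent of everything; under `"MAR"` the
#' missingness probability follows a logit model in standardised age
#' (slope 0.5 per 10 years) with the intercept calibrated so the marginal
#' rate matches the requested one.
#'
#' @param covariates data.frame with columns among `bmi`, `tc`, `tg`,
#'   `ldl` (numeric) and `smoking` (character).
#' @param missing_rates named rates in `[0,1]`.
#' @param seed integer seed.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param age_z standardised age vector, required for `"MAR"`.
#' @return `covariates` with masked entries (`NA` for numeric, `"missing"`
#'   for smoking).
#' @export
inject_missingness <- function(covariates, missing_rates, seed = 1L,
                               mechanism = c("MCAR", "MAR"),
                               age_z = NULL) {
  mechanism <- match.arg(mechanism)
  .assert(all(missing_rates >= 0 & missing_rates <= 1),
          "missing_rates must lie in [0,1]")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(covariates)
  for (v in intersect(names(missing_rates), names(covariates))) {
    rate <- missing_rates[[v]]
    if (mechanism == "MCAR" || rate %in% c(0, 1)) {
      mask <- stats::runif(n) < rate
    } else {
      .assert(!is.null(age_z), "MAR missingness needs age_z")
      # calibrate the intercept so the mean probability equals the rate
      a <- stats::uniroot(function(a)
        mean(stats::plogis(a + 0.5 * age_z)) - rate, c(-20, 20))$root
      mask <- stats::runif(n) < stats::plogis(a + 0.5 * age_z)
    }
    if (v == "smoking") covariates[[v]][mask] <- "missing"
    else covariates[[v]][mask] <- NA_real_
  }
  covariates
}

#' Simulate a synthetic EHR cohort with known causal ground truth
#'
#' Generates the three raw tables (patients, clinical events,
#' measurements) for `config$n_patients` patients. Per patient: a latent
#' multimorbidity score `U ~ N(0,1)`; age uniform on the configured
#' bounds; underlying SBP `140 + 8 * age_z - confounding_sbp * U +
#' person-level noise`; repeated SBP readings around it inside the
#' exposure window; a pre-baseline diagnosis/medication token stream whose
#' intensity and chronic-disease share increase with U; baseline
#' medication codes (antihypertensive use increasing with SBP,
#' beta-blocker/LABA/inhaled corticosteroid at fixed rates); BMI and lipid
#' measurements before baseline with missingness at the configured rates;
#' and a binary cardiovascular outcome drawn from the log-link model in
#' [oracle_marginal_rr()], materialised as an endpoint event inside the
#' 1--6-year follow-up window. A configurable fraction of patients has an
#' event or deregistration inside the exposure period, exercising the
#' early-exclusion path.
#'
#' @param config a [sim_config()].
#' @param oracle_draws Monte-Carlo draws for the attached ground truth.
#' @return list with `patients`, `events`, `measurements` (as in
#'   [read_tables()]), `truth` (a `sim_truth` with per-patient diagnostics
#'   in `truth$patient`: latent score, underlying SBP, number of readings,
#'   assigned category, outcome, true propensities `g_true` and true
#'   outcome probabilities `q_true`), and `config`.
#' @export
simulate_ehr <- function(config, oracle_draws = 2e5) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  cfg <- config
  run <- cfg$run
  n <- cfg$n_patients
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  k6 <- length(cfg$true_log_rr)
  edges <- run$category_edges

  u <- stats::rnorm(n)
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(0.465, 0.535))
  age <- sample(run$age_bounds[1]:run$age_bounds[2], n, replace = TRUE)
  span <- as.integer(run$date_window[2] - run$date_window[1])
  baseline <- run$date_window[1] + sample.int(span + 1L, n, replace = TRUE) - 1L
  yob <- as.integer(format(baseline, "%Y")) - age
  hist_years <- stats::runif(n, cfg$history_years[1], cfg$history_years[2])
  reg_start <- baseline - as.integer(round(hist_years * .DAYS_YEAR))
  fu_end_days <- run$followup_start_days + run$followup_span_days
  reg_end <- baseline + fu_end_days + sample.int(366L, n, replace = TRUE) - 1L

  # exposure-period events/exits (excluded downstream)
  early <- stats::runif(n) < cfg$early_exit_rate
  early_kind <- ifelse(early & stats::runif(n) < 0.5, "event", "exit")
  early_kind[!early] <- "none"
  exit_day <- sample(30:(run$exposure_days - 1L), n, replace = TRUE)
  reg_end[early_kind == "exit"] <-
    baseline[early_kind == "exit"] + exit_day[early_kind == "exit"]
  if (cfg$followup_exit_rate > 0) {
    fx <- early_kind == "none" &
      stats::runif(n) < cfg$followup_exit_rate
    reg_end[fx] <- baseline[fx] +
      sample(run$followup_start_days:(fu_end_days - 1L), sum(fx),
             replace = TRUE)
  }

  # One-sided frailty link: multimorbidity (U > 0) drags blood pressure
  # down -- the reverse-causality mechanism behind spurious J-shapes --
  # while good health does not push it up. Centred so E[SBP | age] = 140.
  s0 <- 140 + 8 * .age_z(age) -
    cfg$confounding_sbp * (.softplus(u) - .SOFTPLUS_MEAN) +
    stats::rnorm(n, sd = cfg$sbp_person_sd)

  # SBP readings: first reading defines baseline (day 0)
  m <- pmax(1L, stats::rpois(n, cfg$measurements_per_patient))
  sbp_pid <- rep(seq_len(n), m)
  offs <- unlist(lapply(m, function(mi) {
    if (mi == 1L) 0L else c(0L, sort(sample(1:(run$exposure_days - 1L),
                                            mi - 1L)))
  }))
  sbp_val <- s0[sbp_pid] + stats::rnorm(length(sbp_pid),
                                        sd = cfg$sbp_noise_sd)
  sbp_date <- baseline[sbp_pid] + offs
  keep_meas <- sbp_date <= reg_end[sbp_pid]   # exits stop measurement

  # category assignment mirrors the cohort builder: clean then average
  valid <- sbp_val >= run$sbp_valid_range[1] &
    sbp_val <= run$sbp_valid_range[2] & keep_meas
  mean_sbp <- rep(NA_real_, n)
  agg <- tapply(sbp_val[valid], sbp_pid[valid], mean)
  mean_sbp[as.integer(names(agg))] <- agg
  cat_idx <- ifelse(is.na(mean_sbp), NA_integer_,
                    findInterval(mean_sbp, edges) + 1L)

  # outcome from the log-link model at the assigned category
  p_event <- rep(NA_real_, n)
  ok <- !is.na(cat_idx)
  p_raw <- cfg$baseline_risk *
    exp(ifelse(ok, cfg$true_log_rr[ifelse(ok, cat_idx, 1L)], 0) +
          cfg$confounding_outcome * u + cfg$age_log_risk * .age_z(age))
  clipped <- mean(p_raw[ok] > cfg$risk_cap)
  .assert(clipped <= 0.05,
          paste0("config error: ", round(100 * clipped, 1),
                 "%% of event probabilities exceed risk_cap; ",
                 "use smaller coefficients"))
  p_event[ok] <- pmin(cfg$risk_cap, p_raw[ok])
  y <- rep(NA_integer_, n)
  y[ok] <- stats::rbinom(sum(ok), 1L, p_event[ok])

  # true per-patient heads for double-robustness checks
  se_m <- cfg$sbp_noise_sd / sqrt(m)
  cuts <- c(-Inf, edges, Inf)
  g_true <- vapply(seq_len(k6), function(k)
    stats::pnorm((cuts[k + 1L] - s0) / se_m) -
      stats::pnorm((cuts[k] - s0) / se_m), numeric(n))
  q_true <- vapply(seq_len(k6), function(k) .risk(cfg, k, u, age),
                   numeric(n))

  # pre-baseline token stream: intensity and chronic share rise with U
  n_tok <- stats::rpois(n, hist_years * cfg$tokens_per_year *
                          exp(cfg$token_rate_loading * u))
  tok_pid <- rep(seq_len(n), n_tok)
  p_chronic <- stats::plogis(stats::qlogis(cfg$chronic_share) +
                               cfg$chronic_loading * u)
  is_chr <- stats::runif(length(tok_pid)) < p_chronic[tok_pid]
  tok_code <- character(length(tok_pid))
  tok_code[is_chr] <- sample(.CHRONIC_CODES, sum(is_chr), replace = TRUE)
  tok_code[!is_chr] <- sprintf("D%03d", sample.int(cfg$vocab_size,
                                                   sum(!is_chr),
                                                   replace = TRUE))
  hist_len <- as.integer(baseline - reg_start)
  tok_date <- reg_start[tok_pid] +
    floor(stats::runif(length(tok_pid)) * (hist_len[tok_pid] + 1L))
  tok_kind <- ifelse(stats::runif(length(tok_pid)) < 0.8,
                     "diagnosis", "medication")
  tok_kind[is_chr] <- "diagnosis"

  ev_pid <- tok_pid; ev_code <- tok_code
  ev_date <- tok_date; ev_kind <- tok_kind
  ev_source <- rep("primary_care", length(tok_pid))

  add_events <- function(pid, code, date, kind, source) {
    ev_pid <<- c(ev_pid, pid); ev_code <<- c(ev_code, code)
    ev_date <<- c(ev_date, date); ev_kind <<- c(ev_kind, kind)
    ev_source <<- c(ev_source, source)
  }

  # cohort-defining COPD code for everyone, dated pre-baseline
  copd_date <- reg_start + floor(stats::runif(n) * (hist_len + 1L))
  add_events(seq_len(n), rep("COPD", n), copd_date,
             rep("diagnosis", n), rep("primary_care", n))

  # baseline medications
  pre_date <- function(idx) reg_start[idx] +
    floor(stats::runif(length(idx)) * (hist_len[idx] + 1L))
  for (med in list(c("BETABLOCKER", 0.20), c("LABA", 0.14),
                   c("ICS", 0.57))) {
    has <- which(stats::runif(n) < as.numeric(med[2]))
    add_events(has, rep(med[1], length(has)), pre_date(has),
               rep("medication", length(has)),
               rep("primary_care", length(has)))
  }
  p_aht <- stats::plogis(stats::qlogis(cfg$antihypertensive_base) +
                           cfg$antihypertensive_slope * (s0 - 140))
  aht_base <- stats::runif(n) < p_aht
  idx <- which(aht_base)
  add_events(idx, rep("ANTIHTN", length(idx)), pre_date(idx),
             rep("medication", length(idx)),
             rep("primary_care", length(idx)))
  # antihypertensive use during follow-up, correlated with baseline use
  p_fu <- ifelse(aht_base, 0.9, 0.05)
  fu_ok <- reg_end >= baseline + run$followup_start_days + 1L
  aht_fu <- which(stats::runif(n) < p_fu & fu_ok)
  if (length(aht_fu)) {
    fu_span <- pmin(as.integer(reg_end[aht_fu] - baseline[aht_fu]),
                    fu_end_days) - run$followup_start_days
    d <- baseline[aht_fu] + run$followup_start_days +
      floor(stats::runif(length(aht_fu)) * pmax(fu_span, 1L))
    add_events(aht_fu, rep("ANTIHTN", length(aht_fu)), d,
               rep("medication", length(aht_fu)),
               rep("primary_care", length(aht_fu)))
  }

  # early exposure-period endpoint events
  ee <- which(early_kind == "event")
  if (length(ee)) {
    add_events(ee, sample(.OUTCOME_CODES, length(ee), replace = TRUE),
               baseline[ee] + sample.int(run$exposure_days - 1L,
                                         length(ee), replace = TRUE),
               rep("diagnosis", length(ee)),
               rep("primary_care", length(ee)))
  }

  # outcome endpoint events inside the follow-up window
  oe <- which(!is.na(y) & y == 1L & early_kind != "exit" &
                reg_end >= baseline + fu_end_days)
  if (length(oe)) {
    type <- sample(.OUTCOME_CODES, length(oe), replace = TRUE,
                   prob = c(0.45, 0.25, 0.2, 0.1))
    d <- baseline[oe] + run$followup_start_days +
      sample.int(run$followup_span_days, length(oe), replace = TRUE) - 1L
    src <- ifelse(type == "CVDEATH", "mortality",
                  ifelse(stats::runif(length(oe)) < 0.6, "primary_care",
                         "secondary_care"))
    add_events(oe, type, d, rep("diagnosis", length(oe)), src)
  }

  # covariate measurements (BMI and lipids) in the 36 months pre-baseline
  cov_mean <- list(bmi = 26 - 0.3 * u, tc = rep(5.3, n),
                   tg = rep(1.6, n), ldl = rep(3.1, n))
  cov_sd <- c(bmi = 1.5, tc = 0.45, tg = 0.25, ldl = 0.15)
  covariates <- data.frame(bmi = cov_mean$bmi + stats::rnorm(n, sd = 0.5),
                           tc = cov_mean$tc + stats::rnorm(n, sd = 0.2),
                           tg = cov_mean$tg + stats::rnorm(n, sd = 0.1),
                           ldl = cov_mean$ldl + stats::rnorm(n, sd = 0.08),
                           smoking = sample(c("current", "former", "never"),
                                            n, replace = TRUE,
                                            prob = c(0.46, 0.37, 0.17)))
  covariates <- inject_missingness(covariates, cfg$missing_rates,
                                   seed = cfg$seed + 7L,
                                   mechanism = cfg$missing_mechanism,
                                   age_z = .age_z(age))
  ms_pid <- integer(); ms_kind <- character(); ms_date <- as.Date(character())
  ms_val <- numeric()
  lookback <- run$covariate_lookback_days
  for (v in c("bmi", "tc", "tg", "ldl")) {
    has <- which(!is.na(covariates[[v]]))
    nm <- sample(1:3, length(has), replace = TRUE)
    pid <- rep(has, nm)
    lo <- pmax(as.integer(baseline[pid] - reg_start[pid]) - 1L,
               0L) # days available before baseline
    back <- pmin(lo, lookback - 1L)
    d <- baseline[pid] - 1L - floor(stats::runif(length(pid)) * (back + 1L))
    val <- covariates[[v]][pid] + stats::rnorm(length(pid),
                                               sd = cov_sd[[v]] / 3)
    ms_pid <- c(ms_pid, pid); ms_kind <- c(ms_kind, rep(v, length(pid)))
    ms_date <- c(ms_date, d); ms_val <- c(ms_val, val)
  }

  pid_str <- sprintf("P%06d", seq_len(n))
  patients <- data.frame(patient_id = pid_str, sex = sex,
                         year_of_birth = yob,
                         smoking = as.character(covariates$smoking),
                         registration_start = reg_start,
                         registration_end = reg_end,
                         stringsAsFactors = FALSE)
  events <- data.frame(patient_id = pid_str[ev_pid], date = ev_date,
                       code = ev_code, kind = ev_kind, source = ev_source,
                       stringsAsFactors = FALSE)
  events <- events[order(events$patient_id, events$date, events$code), ]
  rownames(events) <- NULL
  measurements <- data.frame(
    patient_id = c(pid_str[sbp_pid[keep_meas]], pid_str[ms_pid]),
    date = c(sbp_date[keep_meas], ms_date),
    kind = c(rep("sbp", sum(keep_meas)), ms_kind),
    value = c(round(sbp_val[keep_meas], 1), round(ms_val, 2)),
    stringsAsFactors = FALSE)
  measurements <- measurements[order(measurements$patient_id,
                                     measurements$date,
                                     measurements$kind), ]
  rownames(measurements) <- NULL

  truth <- oracle_marginal_rr(cfg, n_draws = oracle_draws)
  truth$patient <- data.frame(patient_id = pid_str, latent = u,
                              underlying_sbp = s0, n_sbp = m,
                              mean_sbp = mean_sbp, category = cat_idx,
                              p_event = p_event, y = y,
                              early = early_kind,
                              stringsAsFactors = FALSE)
  truth$g_true <- g_true
  truth$q_true <- q_true

  list(patients = patients, events = events, measurements = measurements,
       truth = truth, config = cfg)
}
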