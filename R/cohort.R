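# Cohort construction: SBP cleaning and averaging, index dates, exposure
# categories, outcome ascertainment in the 1--6-year window, exclusions,
# covariates, and the selection flowchart.

#' Clean systolic blood pressure measurements
#'
#' Retains SBP readings with values inside the plausible range (inclusive
#' at both ends; the default drops readings `<50` or `>300` mm Hg).
#' Row order is preserved.
#'
#' @param measurements measurement data.frame (see [read_tables()]); only
#'   rows with `kind == "sbp"` are considered.
#' @param range inclusive valid range, mm Hg.
#' @return the SBP rows with in-range values.
#' @export
clean_sbp <- function(measurements, range = c(50, 300)) {
  sbp <- measurements[measurements$kind == "sbp", , drop = FALSE]
  sbp[sbp$value >= range[1] & sbp$value <= range[2], , drop = FALSE]
}

# same-day readings are averaged into one reading dated that day
.collapse_same_day <- function(dates, values) {
  v <- tapply(values, as.integer(dates), mean)
  d <- as.Date(as.integer(names(v)), origin = "1970-01-01")
  o <- order(d)
  list(date = d[o], value = as.numeric(v)[o])
}

#' Index date, exposure average and category for one patient
#'
#' The baseline (index date) is the date of the patient's first cleaned
#' SBP reading inside the eligible date window at which their age is
#' within bounds; same-day readings count as one reading (their mean).
#' The exposure value is the arithmetic mean of cleaned readings dated in
#' `[baseline, baseline + exposure_days)`, categorised with
#' [sbp_category()].
#'
#' @param patient one row of the patients table.
#' @param sbp_measurements cleaned SBP rows for this patient.
#' @param config a [run_config()].
#' @return list with `baseline_date`, `age`, `mean_sbp`, `category`, or
#'   an object of class `ineligible` (with attribute `reason`) when the
#'   patient has no eligible reading.
#' @export
index_and_exposure <- function(patient, sbp_measurements, config) {
  ineligible <- function(reason)
    structure(list(), class = "ineligible", reason = reason)
  if (nrow(sbp_measurements) == 0L)
    return(ineligible("no valid SBP measurement"))
  cd <- .collapse_same_day(sbp_measurements$date, sbp_measurements$value)
  in_window <- cd$date >= config$date_window[1] &
    cd$date <= config$date_window[2]
  age_at <- as.integer(format(cd$date, "%Y")) - patient$year_of_birth
  eligible <- in_window & age_at >= config$age_bounds[1] &
    age_at <= config$age_bounds[2]
  if (!any(eligible))
    return(ineligible("no eligible SBP in date window"))
  i0 <- which(eligible)[1]
  baseline <- cd$date[i0]
  in_exp <- cd$date >= baseline &
    cd$date < baseline + config$exposure_days
  mean_sbp <- mean(cd$value[in_exp])
  list(baseline_date = baseline, age = age_at[i0], mean_sbp = mean_sbp,
       category = sbp_category(mean_sbp, config$category_edges))
}

#' Ascertain cardiovascular outcomes for one patient
#'
#' A patient is positive for an endpoint iff any qualifying event (per the
#' code-list classes `ihd`, `hf`, `stroke`, `cv_death`, from any source)
#' is dated in `[baseline + followup_start_days, baseline +
#' followup_start_days + followup_span_days)`. The primary outcome is the
#' union of the four endpoint classes. Qualifying events inside the
#' exposure period flag the patient for early exclusion.
#'
#' @param events event rows for one patient.
#' @param baseline the patient's index date.
#' @param config a [run_config()].
#' @param codelists code-list table (see [default_codelists()]).
#' @param registration_start registration start date (events before it are
#'   an integrity error).
#' @return list of outcome flags, `first_event_date` (first qualifying
#'   event on/after baseline, or `NA`), and `early_event`.
#' @export
ascertain_outcomes <- function(events, baseline, config,
                               codelists = default_codelists(),
                               registration_start = NULL) {
  if (!is.null(registration_start) && nrow(events) &&
      any(events$date < registration_start))
    stop("integrity error: event dated before registration_start",
         call. = FALSE)
  cls <- codelists$class[match(events$code, codelists$code)]
  cls[is.na(cls)] <- "other"
  qualifying <- cls %in% c("ihd", "hf", "stroke", "cv_death")
  w0 <- baseline + config$followup_start_days
  w1 <- w0 + config$followup_span_days
  in_win <- qualifying & events$date >= w0 & events$date < w1
  flag <- function(x) as.integer(any(in_win & cls == x))
  qual_dates <- events$date[qualifying & events$date >= baseline]
  list(outcome_primary = as.integer(any(in_win)),
       outcome_ihd = flag("ihd"), outcome_hf = flag("hf"),
       outcome_stroke = flag("stroke"), outcome_cvdeath = flag("cv_death"),
       first_event_date = if (length(qual_dates)) min(qual_dates)
                          else as.Date(NA),
       early_event = any(qualifying & events$date >= baseline &
                           events$date < baseline + config$exposure_days))
}

#' Build the analysable cohort and selection flowchart
#'
#' Applies the selection steps in order, recording the number of patients
#' remaining after each: (1) all patients; (2) at least one cleaned SBP
#' reading in the eligible date window with age in bounds, which defines
#' the baseline; (3) COPD code on/before baseline; (4) no qualifying
#' cardiovascular event and no registration exit within the exposure
#' period. Covariates (BMI, TC, TG, LDL) are averaged over measurements
#' strictly before baseline within the look-back window; baseline disease
#' and medication flags come from codes dated on/before baseline;
#' antihypertensive use during follow-up is any antihypertensive code in
#' `[baseline + followup_start_days, registration_end]`.
#'
#' @param tables list with `patients`, `events`, `measurements`.
#' @param config a [run_config()].
#' @param codelists code-list table.
#' @return list with `cohort` (data.frame of class `cohort`) and
#'   `flowchart` (data.frame `step`, `n`).
#' @export
build_cohort <- function(tables, config = run_config(),
                         codelists = default_codelists()) {
  patients <- tables$patients
  events <- tables$events
  sbp <- clean_sbp(tables$measurements, config$sbp_valid_range)
  n0 <- nrow(patients)

  if (nrow(events) &&
      any(events$date < patients$registration_start[
        match(events$patient_id, patients$patient_id)], na.rm = TRUE))
    stop("integrity error: event dated before registration_start",
         call. = FALSE)

  # --- index date and exposure (vectorised over readings) -------------
  pid <- match(sbp$patient_id, patients$patient_id)
  di <- as.integer(sbp$date)
  ok <- !is.na(pid)
  pid <- pid[ok]; di <- di[ok]; val <- sbp$value[ok]
  # same-day readings collapse to their mean, dated that day
  o <- order(pid, di)
  pid <- pid[o]; di <- di[o]; val <- val[o]
  grp <- cumsum(c(TRUE, pid[-1] != pid[-length(pid)] |
                    di[-1] != di[-length(di)]))
  if (length(grp)) {
    val <- as.numeric(rowsum(val, grp) / rowsum(rep(1, length(grp)), grp))
    first <- !duplicated(grp)
    pid <- pid[first]; di <- di[first]
  }
  yr <- as.POSIXlt(as.Date(di, origin = "1970-01-01"))$year + 1900L
  age_at <- yr - patients$year_of_birth[pid]
  eligible <- di >= as.integer(config$date_window[1]) &
    di <= as.integer(config$date_window[2]) &
    age_at >= config$age_bounds[1] & age_at <= config$age_bounds[2]
  bint <- rep(NA_integer_, n0)
  bm <- tapply(di[eligible], pid[eligible], min)
  bint[as.integer(names(bm))] <- as.integer(bm)

  steps <- data.frame(step = "patients", n = n0)
  keep <- !is.na(bint)
  steps <- rbind(steps,
                 data.frame(step = "sbp_in_window_age_in_bounds",
                            n = sum(keep)))

  in_exp <- !is.na(bint[pid]) & di >= bint[pid] &
    di < bint[pid] + config$exposure_days
  ms <- rowsum(val[in_exp], pid[in_exp])
  mc <- rowsum(rep(1, sum(in_exp)), pid[in_exp])
  mean_sbp <- rep(NA_real_, n0)
  mean_sbp[as.integer(rownames(ms))] <- as.numeric(ms / mc)

  baseline <- as.Date(bint, origin = "1970-01-01")
  age <- as.integer(format(baseline, "%Y")) - patients$year_of_birth

  # --- code classes and baseline flags --------------------------------
  cls <- codelists$class[match(events$code, codelists$code)]
  cls[is.na(cls)] <- "other"
  ev_pid <- match(events$patient_id, patients$patient_id)
  ev_di <- as.integer(events$date)
  on_or_before_baseline <- !is.na(ev_pid) & !is.na(bint[ev_pid]) &
    ev_di <= bint[ev_pid]

  has_code_by <- function(class_name, rows) {
    out <- logical(n0)
    out[unique(ev_pid[rows & cls == class_name])] <- TRUE
    out
  }
  copd <- has_code_by("copd", on_or_before_baseline)
  keep <- keep & copd
  steps <- rbind(steps, data.frame(step = "copd_at_baseline",
                                   n = sum(keep)))

  # --- outcomes in the follow-up window, early exclusions -------------
  qualifying <- cls %in% c("ihd", "hf", "stroke", "cv_death") &
    !is.na(ev_pid) & !is.na(bint[ev_pid])
  w0 <- bint[ev_pid] + config$followup_start_days
  in_win <- qualifying & ev_di >= w0 &
    ev_di < w0 + config$followup_span_days
  out_flag <- function(class_name) {
    out <- integer(n0)
    out[unique(ev_pid[in_win & cls == class_name])] <- 1L
    out
  }
  outcome_ihd <- out_flag("ihd"); outcome_hf <- out_flag("hf")
  outcome_stroke <- out_flag("stroke")
  outcome_cvdeath <- out_flag("cv_death")
  outcome_primary <- integer(n0)
  outcome_primary[unique(ev_pid[in_win])] <- 1L
  qpost <- qualifying & ev_di >= bint[ev_pid]
  fed <- rep(NA_integer_, n0)
  fm <- tapply(ev_di[qpost], ev_pid[qpost], min)
  fed[as.integer(names(fm))] <- as.integer(fm)
  first_event_date <- as.Date(fed, origin = "1970-01-01")

  early_event <- logical(n0)
  early_event[unique(ev_pid[qualifying & ev_di >= bint[ev_pid] &
                              ev_di < bint[ev_pid] +
                                config$exposure_days])] <- TRUE
  early_exit <- keep &
    patients$registration_end < baseline + config$exposure_days
  keep <- keep & !early_event & !early_exit
  steps <- rbind(steps,
                 data.frame(step = "no_event_or_exit_in_exposure",
                            n = sum(keep)))
  if (!any(keep))
    stop("empty cohort after selection; review the configuration",
         call. = FALSE)

  sel <- which(keep)
  # covariate means strictly before baseline within the look-back window
  meas <- tables$measurements
  cov_val <- function(kind_name) {
    rows <- which(meas$kind == kind_name)
    mpid <- match(meas$patient_id[rows], patients$patient_id)
    mdi <- as.integer(meas$date[rows])
    okc <- !is.na(mpid) & !is.na(bint[mpid]) & mdi < bint[mpid] &
      mdi >= bint[mpid] - config$covariate_lookback_days
    v <- tapply(meas$value[rows][okc], mpid[okc], mean)
    out <- rep(NA_real_, n0)
    out[as.integer(names(v))] <- v
    out
  }
  bmi <- cov_val("bmi"); tc <- cov_val("tc"); tg <- cov_val("tg")
  ldl <- cov_val("ldl")

  flag_baseline <- function(class_name)
    as.integer(has_code_by(class_name, on_or_before_baseline))
  # antihypertensive during follow-up
  fu_aht <- logical(n0)
  selrows <- cls == "antihypertensive" & !is.na(ev_pid) &
    !is.na(bint[ev_pid]) &
    ev_di >= bint[ev_pid] + config$followup_start_days &
    ev_di <= as.integer(patients$registration_end[ev_pid])
  fu_aht[unique(ev_pid[selrows])] <- TRUE

  fu_end <- baseline + config$followup_start_days + config$followup_span_days
  exit_date <- pmin(patients$registration_end, fu_end)
  followup_years <- pmax(0, as.numeric(
    exit_date - (baseline + config$followup_start_days))) / .DAYS_YEAR

  cohort <- data.frame(
    patient_id = patients$patient_id[sel],
    baseline_date = baseline[sel],
    age = age[sel],
    sex = patients$sex[sel],
    smoking = patients$smoking[sel],
    mean_sbp = mean_sbp[sel],
    stringsAsFactors = FALSE)
  cohort$category <- sbp_category(cohort$mean_sbp, config$category_edges)
  cohort$registration_start <- patients$registration_start[sel]
  cohort$bmi <- bmi[sel]; cohort$tc <- tc[sel]; cohort$tg <- tg[sel]
  cohort$ldl <- ldl[sel]
  for (fl in c("ihd", "af", "ckd", "diabetes", "ra", "smi"))
    cohort[[paste0("flag_", fl)]] <- flag_baseline(fl)[sel]
  cohort$beta_blocker <- flag_baseline("beta_blocker")[sel]
  cohort$laba <- flag_baseline("laba")[sel]
  cohort$ics <- flag_baseline("ics")[sel]
  cohort$antihypertensive <- flag_baseline("antihypertensive")[sel]
  cohort$antihypertensive_fu <- as.integer(fu_aht[sel])
  cohort$outcome_primary <- outcome_primary[sel]
  cohort$outcome_ihd <- outcome_ihd[sel]
  cohort$outcome_hf <- outcome_hf[sel]
  cohort$outcome_stroke <- outcome_stroke[sel]
  cohort$outcome_cvdeath <- outcome_cvdeath[sel]
  cohort$first_event_date <- first_event_date[sel]
  cohort$exit_date <- exit_date[sel]
  cohort$followup_years <- followup_years[sel]
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort", "data.frame")
  list(cohort = cohort, flowchart = steps)
}
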