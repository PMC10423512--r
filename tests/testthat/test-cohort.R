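test_that("SBP cleaning keeps the inclusive [50, 300] range in order", {
  meas <- data.frame(patient_id = "A",
                     date = as.Date("2000-01-01") + 0:4,
                     kind = "sbp",
                     value = c(49.9, 50, 125, 300, 300.1))
  out <- clean_sbp(meas)
  expect_equal(out$value, c(50, 125, 300))

  expect_equal(nrow(clean_sbp(meas[0, ])), 0)

  set.seed(42)
  v <- runif(1000, 40, 310)
  meas2 <- data.frame(patient_id = "A", date = as.Date("2000-01-01"),
                      kind = "sbp", value = v)
  expect_equal(nrow(clean_sbp(meas2)), sum(v >= 50 & v <= 300))
})

test_that("category edges follow the half-open printed-label convention", {
  x <- c(119.99, 120, 129.9999, 130, 139, 140, 150, 159.5, 160, 250)
  expect_equal(as.character(sbp_category(x)),
               c("<120", "120-129", "120-129", "130-139", "130-139",
                 "140-149", "150-159", "150-159", ">=160", ">=160"))
  # partition: every value in [50, 300] maps to exactly one category
  g <- seq(50, 300, by = 0.25)
  expect_false(anyNA(sbp_category(g)))
})

test_that("index date and exposure mean follow the window rules", {
  cfg <- run_config()
  patient <- data.frame(patient_id = "A", year_of_birth = 1930,
                        stringsAsFactors = FALSE)
  sbp <- data.frame(patient_id = "A",
                    date = as.Date(c("1995-03-01", "1995-06-01",
                                     "1996-02-27", "1996-03-05")),
                    kind = "sbp", value = c(118, 131, 140, 500))
  out <- index_and_exposure(patient, clean_sbp(sbp), cfg)
  expect_equal(out$baseline_date, as.Date("1995-03-01"))
  # 1996-03-05 reading is outside [baseline, baseline + 365); 500 invalid
  expect_equal(out$mean_sbp, mean(c(118, 131, 140)))
  expect_equal(as.character(out$category), "120-129")
  expect_equal(out$age, 65)

  # same-day readings collapse to one reading before averaging
  sbp2 <- data.frame(patient_id = "A",
                     date = as.Date(c("1995-03-01", "1995-03-01",
                                      "1995-04-01")),
                     kind = "sbp", value = c(110, 130, 140))
  out2 <- index_and_exposure(patient, sbp2, cfg)
  expect_equal(out2$mean_sbp, mean(c(120, 140)))

  # single boundary values
  one <- function(v) {
    s <- data.frame(patient_id = "A", date = as.Date("1995-03-01"),
                    kind = "sbp", value = v)
    as.character(index_and_exposure(patient, s, cfg)$category)
  }
  expect_equal(one(119.99), "<120")
  expect_equal(one(160), ">=160")

  # out-of-window or age-ineligible patients are flagged ineligible
  young <- data.frame(patient_id = "B", year_of_birth = 1970,
                      stringsAsFactors = FALSE)
  out3 <- index_and_exposure(young, sbp2, cfg)
  expect_s3_class(out3, "ineligible")
  expect_match(attr(out3, "reason"), "no eligible")
})

test_that("outcomes are captured only inside the 1-6 year window", {
  cfg <- run_config()
  b <- as.Date("1995-03-01")
  mk <- function(code, offset)
    data.frame(patient_id = "A", date = b + offset, code = code,
               kind = "diagnosis", source = "primary_care",
               stringsAsFactors = FALSE)
  # in-window stroke
  out <- ascertain_outcomes(mk("STROKE", 400), b, cfg)
  expect_equal(out$outcome_stroke, 1L)
  expect_equal(out$outcome_primary, 1L)
  expect_false(out$early_event)
  # pre-window IHD only: no outcome, flagged for early exclusion
  out <- ascertain_outcomes(mk("IHD", 200), b, cfg)
  expect_equal(out$outcome_primary, 0L)
  expect_true(out$early_event)
  # past-window cardiovascular death
  out <- ascertain_outcomes(mk("CVDEATH", 2200), b, cfg)
  expect_equal(out$outcome_primary, 0L)
  # window start day is included, end day is not
  expect_equal(ascertain_outcomes(mk("HF", 365), b, cfg)$outcome_hf, 1L)
  expect_equal(ascertain_outcomes(mk("HF", 2190), b, cfg)$outcome_hf, 0L)
  # event before registration start is an integrity error
  expect_error(
    ascertain_outcomes(mk("HF", 400), b, cfg,
                       registration_start = b + 500),
    "integrity error")
})

test_that("cohort selection reproduces a hand-labelled 10-patient fixture", {
  cfg <- run_config()
  b <- as.Date("1995-06-01")
  mkp <- function(id, yob = 1930, rs = "1990-01-01", re = "2005-01-01")
    data.frame(patient_id = id, sex = "female", year_of_birth = yob,
               smoking = "never", registration_start = as.Date(rs),
               registration_end = as.Date(re), stringsAsFactors = FALSE)
  patients <- do.call(rbind, list(
    mkp("P01"), mkp("P02"), mkp("P03", yob = 1970),  # P03 too young
    mkp("P04"), mkp("P05"), mkp("P06"),
    mkp("P07", re = "1995-08-01"),                   # exits in exposure
    mkp("P08"), mkp("P09"), mkp("P10")))
  # everyone has an SBP reading except P04; P05's is out of range
  sbp_ids <- c("P01", "P02", "P03", "P05", "P06", "P07", "P08", "P09",
               "P10")
  measurements <- data.frame(
    patient_id = sbp_ids, date = b, kind = "sbp",
    value = c(125, 150, 130, 40, 118, 135, 160, 142, 128),
    stringsAsFactors = FALSE)
  # all but P06 have COPD before baseline; P08 has an early IHD event
  ev_ids <- setdiff(paste0("P", sprintf("%02d", 1:10)), "P06")
  events <- rbind(
    data.frame(patient_id = ev_ids, date = as.Date("1992-01-01"),
               code = "COPD", kind = "diagnosis",
               source = "primary_care", stringsAsFactors = FALSE),
    data.frame(patient_id = c("P08", "P09"), date = c(b + 100, b + 500),
               code = "IHD", kind = "diagnosis", source = "primary_care",
               stringsAsFactors = FALSE))
  built <- build_cohort(list(patients = patients, events = events,
                             measurements = measurements), cfg)
  # hand count: start 10; SBP+age eligible removes P04 (none), P05
  # (invalid value), P03 (age 25) -> 7; COPD removes P06 -> 6; early
  # event/exit removes P07, P08 -> 4
  expect_equal(built$flowchart$n, c(10, 7, 6, 4))
  expect_setequal(built$cohort$patient_id, c("P01", "P02", "P09", "P10"))
  # flowchart is nonincreasing and ends at the cohort size
  expect_true(all(diff(built$flowchart$n) <= 0))
  expect_equal(tail(built$flowchart$n, 1), nrow(built$cohort))
  # P09's in-window IHD event is an outcome
  expect_equal(built$cohort$outcome_ihd[built$cohort$patient_id == "P09"],
               1L)
})

test_that("vectorised builder agrees with per-patient operations on simulated data", {
  sim <- sim_null_small()
  coh <- sim$built$cohort
  cfg <- sim$config$run
  sbp <- clean_sbp(sim$measurements, cfg$sbp_valid_range)
  idx <- sample(nrow(coh), 25)
  for (i in idx) {
    pid <- coh$patient_id[i]
    prow <- sim$patients[sim$patients$patient_id == pid, ]
    ie <- index_and_exposure(prow, sbp[sbp$patient_id == pid, ], cfg)
    expect_equal(ie$baseline_date, coh$baseline_date[i])
    expect_equal(ie$mean_sbp, coh$mean_sbp[i])
    expect_equal(as.character(ie$category),
                 as.character(coh$category[i]))
    ao <- ascertain_outcomes(
      sim$events[sim$events$patient_id == pid, ], coh$baseline_date[i],
      cfg)
    expect_equal(ao$outcome_primary, coh$outcome_primary[i])
    expect_equal(ao$first_event_date, coh$first_event_date[i])
  }
})

test_that("exposure-period exclusions match the generator's rate", {
  sim <- sim_null_small()
  fc <- sim$built$flowchart
  n_before <- fc$n[fc$step == "copd_at_baseline"]
  n_after <- fc$n[fc$step == "no_event_or_exit_in_exposure"]
  excluded <- n_before - n_after
  rate <- sim$config$early_exit_rate
  # binomial 99.9% band around the configured early-exit rate
  expect_gt(excluded, n_before * rate - 3.3 * sqrt(n_before * rate))
  expect_lt(excluded, n_before * rate + 3.3 * sqrt(n_before * rate))
})

test_that("category counts partition the cohort", {
  sim <- sim_null_small()
  coh <- sim$built$cohort
  expect_equal(sum(table(coh$category)), nrow(coh))
  expect_false(anyNA(coh$category))
  expect_true(all(coh$mean_sbp >= 50 & coh$mean_sbp <= 300))
})
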