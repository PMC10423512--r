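mk_sens_cohort <- function() {
  b <- as.Date("1998-06-01")
  data.frame(
    patient_id = sprintf("P%02d", 1:10),
    baseline_date = b + c(0, 0, 0, 0, 0, 1200, 1200, 1200, 0, 0),
    smoking = c("never", "never", rep("current", 4), rep("former", 4)),
    antihypertensive_fu = c(1, 0, 0, 1, 0, 0, 0, 1, 0, 0),
    first_event_date = c(b + 400, b + 800, NA, b + 1400, b + 370,
                         NA, NA, NA, b + 700, NA),
    category = sbp_category(c(115, 125, 135, 145, 155, 165, 125, 135,
                              145, 155)),
    stringsAsFactors = FALSE)
}

test_that("the five sensitivity filters apply their exact predicates", {
  coh <- mk_sens_cohort()
  # two never-smokers among ten
  expect_equal(nrow(sensitivity_filter(coh, "smokers_only")), 8)
  # three users of antihypertensives during follow-up
  expect_equal(nrow(sensitivity_filter(coh, "no_antihypertensive")), 7)
  # baselines in 1998 vs 2001-09: three post-2001
  expect_equal(nrow(sensitivity_filter(coh, "post_2001")), 3)
  # first-year-of-follow-up events: first_event_date in
  # [baseline + 365, baseline + 730): P01 (400), P05 (370), P09 (700)
  s12 <- sensitivity_filter(coh, "exclude_12m_events")
  expect_setequal(setdiff(coh$patient_id, s12$patient_id),
                  c("P01", "P05", "P09"))
  # first two years: additionally P02 (800)
  s24 <- sensitivity_filter(coh, "exclude_24m_events")
  expect_setequal(setdiff(coh$patient_id, s24$patient_id),
                  c("P01", "P02", "P05", "P09"))
  expect_error(sensitivity_filter(coh, "bogus"), "unknown sensitivity")
})

test_that("an emptied subset warns", {
  coh <- mk_sens_cohort()
  coh$baseline_date <- as.Date("1995-01-01")
  expect_warning(out <- sensitivity_filter(coh, "post_2001"), "empty")
  expect_equal(nrow(out), 0)
})

test_that("sensitivity filters agree with an independent recount on simulated data", {
  sim <- sim_null_small()
  coh <- sim$built$cohort
  s12 <- sensitivity_filter(coh, "exclude_12m_events")
  drop <- !is.na(coh$first_event_date) &
    coh$first_event_date >= coh$baseline_date + 365 &
    coh$first_event_date < coh$baseline_date + 730
  expect_equal(nrow(s12), sum(!drop))
  expect_setequal(s12$patient_id, coh$patient_id[!drop])
})

test_that("descriptives reproduce published-style percentages and quantiles", {
  # published category counts: percentages recomputed at one decimal
  counts <- c(3943, 5870, 8097, 9050, 6101, 6541)
  pct <- round(100 * counts / sum(counts), 1)
  expect_equal(pct, c(10.0, 14.8, 20.4, 22.9, 15.4, 16.5))
  expect_equal(sum(counts), 39602)

  # the quantile convention is linear interpolation (type 7)
  x <- 1:100
  q <- drcohort:::.q_iqr(x)
  expect_equal(q, c(50.5, 25.75, 75.25))

  coh <- mk_sens_cohort()
  coh$age <- 60:69
  coh$sex <- rep(c("female", "male"), 5)
  coh$followup_years <- 5
  coh$bmi <- coh$tc <- coh$tg <- coh$ldl <- NA_real_
  coh$flag_ihd <- coh$flag_ckd <- coh$flag_diabetes <- coh$flag_smi <-
    coh$flag_af <- 0L
  coh$antihypertensive <- coh$ics <- coh$laba <- coh$beta_blocker <- 0L
  desc <- describe_cohort(coh)
  expect_equal(sum(desc$stats$n), nrow(coh))
  expect_equal(sum(desc$stats$pct), 100, tolerance = 0.3)

  # single-patient cohort: median equals the value, IQR degenerate
  one <- coh[3, ]
  one$age <- 72
  d1 <- describe_cohort(one)
  expect_equal(unname(d1$stats$age["130-139", ]), c(72, 72, 72))
})

test_that("smoking percentages are reported under both denominators", {
  coh <- mk_sens_cohort()
  coh$age <- 65
  coh$sex <- "female"
  coh$followup_years <- 5
  coh$bmi <- coh$tc <- coh$tg <- coh$ldl <- NA_real_
  coh$flag_ihd <- coh$flag_ckd <- coh$flag_diabetes <- coh$flag_smi <-
    coh$flag_af <- 0L
  coh$antihypertensive <- coh$ics <- coh$laba <- coh$beta_blocker <- 0L
  coh$smoking[1] <- "missing"
  desc <- describe_cohort(coh)
  sm <- desc$stats$smoking_current
  # categories with a missing-smoking patient have a larger share of
  # known than of all patients
  expect_true(all(sm$pct_of_known >= sm$pct_of_category))
})

test_that("forest tables render estimates in the standard format", {
  rr <- data.frame(analysis = "dr", category = levels(sbp_category(120)),
                   n = c(100, 200, 300, 300, 200, 150),
                   events = c(10, 18, 30, 33, 24, 21),
                   rr = c(0.99, 1, 1.02, 1.07, 1.11, 1.16),
                   ci_low = c(0.93, NA, 0.97, 1.01, 1.05, 1.10),
                   ci_high = c(1.05, NA, 1.07, 1.12, 1.17, 1.22),
                   reference = c(FALSE, TRUE, rep(FALSE, 4)),
                   stringsAsFactors = FALSE)
  class(rr) <- c("rr_table", "data.frame")
  ft <- forest_table(rr)
  expect_equal(ft$estimate[6], "1.16 (1.10 to 1.22)")
  expect_equal(ft$estimate[2], "1.00 (reference)")
  expect_true(is.na(ft$ci_low[2]))
  expect_equal(ft$events_n[1], "10/100")
  expect_equal(ft$log_rr, log(ft$rr))
  # empty input gives a header-only table
  empty <- forest_table(list())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("analysis", "estimate", "log_rr") %in% names(empty)))
})
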