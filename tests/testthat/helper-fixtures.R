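# Shared fixtures. Expensive simulated datasets are built lazily once per
# test run and cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cache)) assign(name, expr, envir = .cache)
  get(name, envir = .cache)
}

# a tiny hand-written raw-table fixture: 3 patients
tiny_tables <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C"),
    sex = c("female", "male", "female"),
    year_of_birth = c(1930L, 1940L, 1925L),
    smoking = c("current", "never", "missing"),
    registration_start = as.Date(c("1985-01-01", "1990-06-01",
                                   "1980-03-15")),
    registration_end = as.Date(c("2005-01-01", "2010-06-01",
                                 "2001-12-31")),
    stringsAsFactors = FALSE)
  events <- data.frame(
    patient_id = c("A", "A", "B"),
    date = as.Date(c("1994-05-02", "1999-01-10", "1995-07-20")),
    code = c("COPD", "IHD", "D001"),
    kind = c("diagnosis", "diagnosis", "diagnosis"),
    source = c("primary_care", "secondary_care", "primary_care"),
    stringsAsFactors = FALSE)
  measurements <- data.frame(
    patient_id = c("A", "B", "C"),
    date = as.Date(c("1995-03-01", "1996-08-10", "1992-11-30")),
    kind = c("sbp", "sbp", "bmi"),
    value = c(125, 141.5, 27.3),
    stringsAsFactors = FALSE)
  list(patients = patients, events = events, measurements = measurements)
}

# default-condition confounded-null simulation at moderate size
sim_null_small <- function() cached("sim_null_small", {
  cfg <- sim_config(n_patients = 6000, seed = 301)
  sim <- simulate_ehr(cfg, oracle_draws = 5e4)
  sim$built <- build_cohort(sim, cfg$run)
  sim
})

# a cohort data.frame built directly (no raw tables) for LR-arm tests
make_cohort_df <- function(n, seed = 1, beta_cat = rep(0, 6),
                           p0 = 0.2, age_beta = 0, bmi_missing = 0) {
  set.seed(seed)
  cat_lev <- levels(sbp_category(120))
  category <- factor(sample(cat_lev, n, replace = TRUE), levels = cat_lev)
  age <- sample(55:90, n, TRUE)
  d <- data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    age = age,
    sex = sample(c("female", "male"), n, TRUE),
    smoking = sample(c("current", "former", "never"), n, TRUE),
    category = category,
    bmi = rnorm(n, 26, 2), tc = rnorm(n, 5.3, 0.5),
    tg = rnorm(n, 1.6, 0.3), ldl = rnorm(n, 3.1, 0.2),
    beta_blocker = rbinom(n, 1, 0.2), laba = rbinom(n, 1, 0.15),
    ics = rbinom(n, 1, 0.5),
    flag_af = rbinom(n, 1, 0.05), flag_ra = rbinom(n, 1, 0.03),
    flag_smi = rbinom(n, 1, 0.01), flag_ckd = rbinom(n, 1, 0.01),
    flag_diabetes = rbinom(n, 1, 0.07),
    stringsAsFactors = FALSE)
  eta <- qlogis(p0) + beta_cat[as.integer(category)] +
    age_beta * (age - 70) / 10
  d$outcome_primary <- rbinom(n, 1, plogis(eta))
  if (bmi_missing > 0) d$bmi[runif(n) < bmi_missing] <- NA
  d
}
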