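# The conventional arm: logistic fits, direct standardisation,
# chained-equation imputation and Rubin pooling.

test_that("exposure-only logistic fit reproduces the 2x2 odds ratio", {
  # toy stratum printed as a 2x2 table: category 2 (reference) vs 3
  counts <- c(a = 30, b = 70, c = 45, d = 55)  # events/non-events
  d <- data.frame(
    category = sbp_category(rep(c(125, 135), times = c(100, 100))),
    outcome_primary = c(rep(1:0, c(30, 70)), rep(1:0, c(45, 55))))
  fit <- fit_outcome_lr(d, "crude")
  or_hand <- (45 * 70) / (55 * 30)   # cross-product ad/bc
  co <- coef(fit$fit)
  expect_equal(unname(exp(co[grep("130-139", names(co))])), or_hand,
               tolerance = 1e-8)
})

test_that("null data yield category coefficients near zero", {
  d <- make_cohort_df(8000, seed = 21, p0 = 0.25)
  fit <- fit_outcome_lr(d, "base")
  co <- summary(fit$fit)$coefficients
  cat_rows <- grep("^category", rownames(co))
  expect_true(all(abs(co[cat_rows, "Estimate"]) <=
                    3 * co[cat_rows, "Std. Error"]))
})

test_that("point estimates are invariant to row duplication", {
  d <- make_cohort_df(500, seed = 22, p0 = 0.3)
  f1 <- fit_outcome_lr(d, "base")
  f2 <- fit_outcome_lr(rbind(d, d), "base")
  expect_equal(coef(f1$fit), coef(f2$fit), tolerance = 1e-6)
})

test_that("direct standardisation matches full enumeration", {
  # enumeration oracle: loop patient by patient, set exposure to k, and
  # predict with stats::predict.glm; psi_k is the hand-averaged risk
  d <- make_cohort_df(400, seed = 23, p0 = 0.3,
                      beta_cat = c(0.4, 0, -0.2, 0.1, 0.3, 0.5),
                      age_beta = 0.3)
  fit <- fit_outcome_lr(d, "base")
  std <- standardize_rr(fit, bootstrap_reps = 0)
  lev <- levels(d$category)
  psi_hand <- vapply(seq_along(lev), function(k) {
    ps <- numeric(nrow(fit$data))
    for (i in seq_len(nrow(fit$data))) {
      row <- fit$data[i, ]
      row$category <- factor(lev[k], levels = levels(fit$data$category))
      ps[i] <- stats::predict(fit$fit, newdata = row, type = "response")
    }
    mean(ps)
  }, 0)
  expect_equal(attr(std, "psi"), psi_hand, tolerance = 1e-10)
  expect_equal(std$rr, psi_hand / psi_hand[2], tolerance = 1e-10)
})

test_that("standardisation enumerates exactly on a 4-patient toy", {
  d <- make_cohort_df(200, seed = 53, p0 = 0.3)
  fit <- fit_outcome_lr(d, "base")
  toy <- fit$data[1:4, ]
  lev <- levels(toy$category)
  fit4 <- fit
  fit4$data <- toy
  std <- standardize_rr(fit4, bootstrap_reps = 0)
  psi_hand <- vapply(seq_along(lev), function(k) {
    tot <- 0
    for (i in 1:4) {
      row <- toy[i, ]
      row$category <- factor(lev[k], levels = lev)
      tot <- tot + stats::predict(fit$fit, newdata = row,
                                  type = "response")
    }
    tot / 4
  }, 0)
  # standardize_rr reports categories in the original (unreleveled) order
  ord <- match(levels(d$category), lev)
  expect_equal(unname(attr(std, "psi")), unname(psi_hand[ord]),
               tolerance = 1e-10)
})

test_that("intercept-only standardisation gives unit risk ratios", {
  d <- make_cohort_df(300, seed = 24, p0 = 0.2)
  d$category <- factor("120-129", levels = levels(d$category))
  d$category[1:50] <- "<120"   # two categories so the fit is valid
  fit <- suppressWarnings(fit_outcome_lr(d, "crude"))
  std <- standardize_rr(fit, bootstrap_reps = 0)
  # crude standardised RR equals the ratio of raw event proportions
  raw <- tapply(d$outcome_primary, d$category, mean)
  expect_equal(std$rr[1], unname(raw[1] / raw[2]), tolerance = 1e-10)
})

test_that("crude standardised RR equals raw proportion ratios", {
  d <- make_cohort_df(3000, seed = 25, p0 = 0.25,
                      beta_cat = c(0.3, 0, -0.1, 0.1, 0.2, 0.4))
  fit <- fit_outcome_lr(d, "crude")
  std <- standardize_rr(fit, bootstrap_reps = 0)
  raw <- tapply(d$outcome_primary, d$category, mean)
  expect_equal(std$rr, as.numeric(raw / raw[2]), tolerance = 1e-10)
})

test_that("chained imputation leaves observed values intact and is seeded", {
  d <- make_cohort_df(800, seed = 26, p0 = 0.25, bmi_missing = 0.4)
  spec <- imputation_spec(m = 3, iterations = 3, seed = 7)
  comp <- impute_chained(d, spec)
  expect_length(comp, 3)
  obs <- !is.na(d$bmi)
  for (cc in comp) {
    expect_false(anyNA(cc$bmi))
    expect_equal(cc$bmi[obs], d$bmi[obs])
  }
  comp2 <- impute_chained(d, spec)
  expect_identical(comp[[2]]$bmi, comp2[[2]]$bmi)
  # no missing data: m identical copies of the input
  d0 <- make_cohort_df(200, seed = 27, p0 = 0.25)
  comp0 <- impute_chained(d0, imputation_spec(m = 2, seed = 1))
  expect_identical(comp0[[1]]$bmi, d0$bmi)
  expect_identical(comp0[[2]]$smoking, d0$smoking)
})

test_that("imputation recovers a known linear relation under MCAR", {
  set.seed(28)
  n <- 3000
  d <- make_cohort_df(n, seed = 28, p0 = 0.2)
  slope <- 0.8
  d$bmi <- 26 + slope * (d$age - 70) / 10 + rnorm(n, sd = 1.5)
  d$bmi[runif(n) < 0.3] <- NA
  comp <- impute_chained(d, imputation_spec(m = 5, iterations = 4,
                                            seed = 9))
  slopes <- vapply(comp, function(cc)
    coef(lm(bmi ~ I((age - 70) / 10), data = cc))[2], 0)
  ses <- vapply(comp, function(cc)
    summary(lm(bmi ~ I((age - 70) / 10),
               data = cc))$coefficients[2, 2], 0)
  expect_lt(abs(mean(slopes) - slope), 2 * mean(ses))
})

test_that("a fully missing variable is an imputation error", {
  d <- make_cohort_df(100, seed = 29, p0 = 0.2)
  d$bmi <- NA_real_
  expect_error(impute_chained(d, imputation_spec(m = 2, seed = 1)),
               "100% missing")
})

test_that("Rubin pooling follows the combination rules", {
  d <- make_cohort_df(600, seed = 30, p0 = 0.25)
  fit <- fit_outcome_lr(d, "crude")
  t1 <- standardize_rr(fit, bootstrap_reps = 40, seed = 1)
  # m identical tables: pooled point equals the common value
  pooled <- pool_rubin(list(t1, t1, t1))
  expect_equal(pooled$rr, t1$rr, tolerance = 1e-12)
  # two tables with log RRs 0 and 0.2 pool to log RR 0.1
  t2 <- t1; t2$rr <- rep(1, 6)
  attr(t2, "se_log") <- rep(0.05, 6)
  t3 <- t1; t3$rr <- exp(rep(0.2, 6)); t3$rr[2] <- 1
  attr(t3, "se_log") <- rep(0.05, 6)
  pooled2 <- pool_rubin(list(t2, t3))
  expect_equal(log(pooled2$rr[-2]), rep(0.1, 5), tolerance = 1e-12)
  # misaligned categories are an integrity error
  t4 <- t1; t4$category <- rev(t4$category)
  expect_error(pool_rubin(list(t1, t4)), "misaligned")
})

test_that("separation is reported with the offending covariate", {
  d <- make_cohort_df(300, seed = 31, p0 = 0.3)
  d$laba <- as.integer(d$outcome_primary == 1)   # perfect separator
  expect_error(suppressWarnings(fit_outcome_lr(d, "base")), "separation")
})
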