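# The encoder's hand-written backpropagation is checked against central
# finite differences on a tiny network, then its statistical behaviour on
# constructed datasets.

tiny_cfg <- function(...) {
  encoder_config(max_sequence_length = 16, embedding_width = 4,
                 n_layers = 2, n_attention_heads = 2, epochs = 1,
                 batch_size = 4, seed = 3, ...)
}

test_that("analytic gradients match finite differences", {
  set.seed(1)
  cfg <- tiny_cfg()
  V <- 12L
  P <- 5L
  lens <- c(6L, 5L, 7L, 4L, 6L)
  bt <- list(tokens = sample(3:V, sum(lens), replace = TRUE),
             age = sample(1:10, sum(lens), replace = TRUE),
             p = rep(seq_len(P), lens), P = P,
             loglen = rnorm(P),
             exposure = sample(1:3, P, replace = TRUE),
             y = rbinom(P, 1, 0.5))
  params <- drcohort:::.enc_init(cfg, V, drcohort:::.N_AGE_BUCKETS, 3,
                                 0.4, c(0.3, 0.3, 0.4))
  mask_sel <- runif(sum(lens)) < 0.3
  g <- drcohort:::.enc_grads(params, bt, cfg, mask_sel)$grads
  lossf <- function(pp)
    drcohort:::.enc_grads(pp, bt, cfg, mask_sel)$loss
  eps <- 1e-6
  check <- function(get, set, gval) {
    x <- get(params)
    for (i in sample(length(x), min(6, length(x)))) {
      pp <- params
      xx <- x; xx[i] <- xx[i] + eps
      lp <- lossf(set(pp, xx))
      xx[i] <- xx[i] - 2 * eps
      lm <- lossf(set(pp, xx))
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - gval[i]),
                1e-4 * max(1, abs(num) + abs(gval[i])))
    }
  }
  for (nm in c("E", "A", "Q", "Wp", "bp", "Wo", "bo", "Wm", "bm"))
    check(function(p) p[[nm]],
          function(p, x) { p[[nm]] <- x; p }, g[[nm]])
  for (l in 1:2) {
    check(function(p) p$W[[l]],
          function(p, x) { p$W[[l]] <- x; p }, g$W[[l]])
    check(function(p) p$b[[l]],
          function(p, x) { p$b[[l]] <- x; p }, g$b[[l]])
  }
})

make_random_cohort <- function(n, seed, n_events = 6) {
  set.seed(seed)
  cat_lev <- levels(sbp_category(120))
  coh <- data.frame(
    patient_id = sprintf("R%05d", seq_len(n)),
    baseline_date = as.Date("2000-01-01"),
    age = sample(55:90, n, TRUE),
    sex = sample(c("female", "male"), n, TRUE),
    smoking = sample(c("current", "former", "never"), n, TRUE),
    category = factor(sample(cat_lev, n, TRUE,
                             prob = c(0.1, 0.15, 0.2, 0.25, 0.15, 0.15)),
                      levels = cat_lev),
    registration_start = as.Date("1995-01-01"),
    stringsAsFactors = FALSE)
  m <- rpois(n, n_events)
  events <- data.frame(
    patient_id = rep(coh$patient_id, m),
    date = as.Date("1999-01-01") + sample(0:300, sum(m), TRUE),
    code = sprintf("D%03d", sample(1:30, sum(m), TRUE)),
    kind = "diagnosis", source = "primary_care",
    stringsAsFactors = FALSE)
  list(cohort = coh, events = events)
}

test_that("propensity head recovers empirical shares when exposure is random", {
  d <- make_random_cohort(5000, 11)
  d$cohort$outcome_primary <- rbinom(5000, 1, 0.2)
  fit <- drseq(d$cohort, d$events,
               encoder_config(epochs = 2, learning_rate = 5e-4, seed = 2,
                              bootstrap_reps = 0),
               crossfit = FALSE)
  shares <- as.numeric(table(d$cohort$category)) / 5000
  dev <- abs(sweep(fit$propensity, 2, shares, `-`))
  expect_lt(max(dev), 0.03)
  # propensities are a distribution for every patient
  expect_equal(rowSums(fit$propensity), rep(1, 5000), tolerance = 1e-8)
})

test_that("outcome heads learn a separable token rule", {
  d <- make_random_cohort(2000, 12)
  has_tok <- vapply(split(d$events$code == "D007",
                          d$events$patient_id),
                    any, TRUE)[d$cohort$patient_id]
  has_tok[is.na(has_tok)] <- FALSE
  d$cohort$outcome_primary <- as.integer(has_tok)
  fit <- drseq(d$cohort, d$events,
               encoder_config(epochs = 20, learning_rate = 5e-3,
                              seed = 4, bootstrap_reps = 0),
               crossfit = FALSE)
  iK <- cbind(seq_len(2000), as.integer(d$cohort$category))
  acc <- mean((fit$outcome_pred[iK] > 0.5) == has_tok)
  expect_gte(acc, 0.99)
})

test_that("training is reproducible and the loss decreases", {
  d <- make_random_cohort(800, 13)
  d$cohort$outcome_primary <- rbinom(800, 1, 0.25)
  cfg <- encoder_config(epochs = 3, seed = 7, bootstrap_reps = 0)
  f1 <- drseq(d$cohort, d$events, cfg, crossfit = FALSE)
  f2 <- drseq(d$cohort, d$events, cfg, crossfit = FALSE)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$rr$rr, f2$rr$rr)
  expect_lt(tail(f1$loss, 1), f1$loss[1])
})

test_that("an empty exposure category is reported by name", {
  d <- make_random_cohort(300, 14)
  d$cohort$category[d$cohort$category == ">=160"] <- "150-159"
  d$cohort$outcome_primary <- rbinom(300, 1, 0.2)
  expect_error(
    drseq(d$cohort, d$events, tiny_cfg(), crossfit = FALSE),
    "zero members")
})
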