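# Conventional-statistics arm: logistic outcome regression with the base
# or expanded covariate set, chained-equation multiple imputation for
# BMI/TC/TG/LDL/smoking, direct standardisation of marginal risk ratios,
# and Rubin pooling across completed datasets.

.BASE_VARS <- c("sex", "age", "bmi", "smoking", "beta_blocker", "laba",
                "ics")
.EXPANDED_VARS <- c(.BASE_VARS, "tg", "ldl", "tc", "flag_af", "flag_ra",
                    "flag_smi", "flag_ckd", "flag_diabetes")

#' Multiple-imputation specification
#'
#' @param m number of imputations (>= 2).
#' @param variables variables to impute; continuous ones use Bayesian
#'   linear regression draws, smoking a multinomial logistic model fitted
#'   on a bootstrap resample of the observed rows.
#' @param iterations chained-equation cycles per imputation.
#' @param seed integer seed.
#' @return object of class `imputation_spec`.
#' @export
imputation_spec <- function(m = 15L,
                            variables = c("bmi", "tc", "tg", "ldl",
                                          "smoking"),
                            iterations = 5L, seed = 1L) {
  .assert(.is_count(m) && m >= 2, "m must be an integer >= 2")
  structure(list(m = as.integer(m), variables = variables,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "imputation_spec")
}

.smoking_factor <- function(x) {
  x[x == "missing"] <- NA
  factor(x, levels = c("never", "current", "former"))
}

# predictor matrix for the conditional imputation models: everything the
# analysis model uses plus exposure and outcome
.imp_design <- function(data, exclude) {
  vars <- c("age", "sex", "category", "outcome_primary",
            setdiff(c("bmi", "tc", "tg", "ldl", "smoking"), exclude))
  vars <- intersect(vars, names(data))
  f <- stats::as.formula(paste("~", paste(vars, collapse = "+")))
  stats::model.matrix(f, data)
}

#' Chained-equation multiple imputation
#'
#' Fills missing covariates by iterated conditional draws: continuous
#' variables by Bayesian linear regression (posterior draws of
#' coefficients and residual variance, imputations with residual noise),
#' smoking status by a multinomial logistic model fitted on a bootstrap
#' resample of the observed rows. Observed values are never altered.
#'
#' @param cohort cohort data.frame (missing values as `NA`; smoking
#'   `"missing"`).
#' @param spec an [imputation_spec()].
#' @return list of `spec$m` completed cohorts (class `mice_set`).
#' @export
impute_chained <- function(cohort, spec = imputation_spec()) {
  data <- as.data.frame(cohort)
  data$smoking <- .smoking_factor(data$smoking)
  cont <- setdiff(intersect(spec$variables, names(data)), "smoking")
  do_smoke <- "smoking" %in% spec$variables
  miss <- lapply(data[cont], is.na)
  if (do_smoke) miss$smoking <- is.na(data$smoking)
  for (v in names(miss))
    .assert(!all(miss[[v]]),
            "imputation error: %s is 100%% missing", v)
  miss <- miss[vapply(miss, any, TRUE)]
  if (length(miss) == 0L) {
    out <- replicate(spec$m, {
      d <- data
      d$smoking <- as.character(d$smoking)
      d$smoking[is.na(d$smoking)] <- "missing"
      d
    }, simplify = FALSE)
    return(structure(out, class = "mice_set", spec = spec))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  completed <- vector("list", spec$m)
  for (im in seq_len(spec$m)) {
    d <- data
    # initial fill: random draws from the observed margins
    for (v in names(miss)) {
      obs <- d[[v]][!miss[[v]]]
      d[[v]][miss[[v]]] <- sample(obs, sum(miss[[v]]), replace = TRUE)
    }
    for (it in seq_len(spec$iterations)) {
      for (v in names(miss)) {
        X <- .imp_design(d, exclude = v)
        mis <- miss[[v]]
        if (v == "smoking") {
          idx <- which(!mis)
          boot <- sample(idx, length(idx), replace = TRUE)
          Xdf <- as.data.frame(X[, -1, drop = FALSE])
          names(Xdf) <- make.names(names(Xdf), unique = TRUE)
          fit <- nnet::multinom(.smk ~ .,
                                data = cbind(.smk = d$smoking[boot],
                                             Xdf[boot, , drop = FALSE]),
                                trace = FALSE, maxit = 200)
          pr <- stats::predict(fit, newdata = Xdf[mis, , drop = FALSE],
                               type = "probs")
          lev <- levels(d$smoking)
          prall <- matrix(0, sum(mis), length(lev),
                          dimnames = list(NULL, lev))
          if (is.null(dim(pr))) {          # two observed classes
            prall[, fit$lev[2]] <- pr
            prall[, fit$lev[1]] <- 1 - pr
          } else prall[, colnames(pr)] <- pr
          draw <- apply(prall, 1, function(p)
            sample(lev, 1, prob = pmax(p, 1e-9)))
          d$smoking[mis] <- factor(draw, levels = lev)
        } else {
          yobs <- d[[v]][!mis]
          Xo <- X[!mis, , drop = FALSE]
          qrX <- qr(Xo)
          bhat <- qr.coef(qrX, yobs)
          bhat[is.na(bhat)] <- 0
          res <- yobs - Xo %*% bhat
          df <- max(length(yobs) - qrX$rank, 1L)
          sigma2 <- sum(res^2) / stats::rchisq(1, df)
          R <- qr.R(qrX)
          keep <- diag(R) != 0
          # draw beta ~ N(bhat, sigma2 (X'X)^-1) via the R factor
          zb <- stats::rnorm(ncol(Xo))
          binc <- tryCatch(backsolve(R, zb) * sqrt(sigma2),
                           error = function(e) rep(0, ncol(Xo)))
          beta <- bhat + binc
          d[[v]][mis] <- as.numeric(X[mis, , drop = FALSE] %*% beta) +
            stats::rnorm(sum(mis), sd = sqrt(sigma2))
        }
      }
    }
    d$smoking <- as.character(d$smoking)
    completed[[im]] <- d
  }
  structure(completed, class = "mice_set", spec = spec)
}

#' Logistic outcome regression with a named predictor set
#'
#' Fits a maximum-likelihood logistic regression of the binary outcome on
#' the 6-level SBP exposure category (reference 120-129 mm Hg) plus the
#' chosen covariate set: `"crude"` (exposure only), `"base"` (sex, age,
#' BMI, smoking, beta-blocker, LABA, inhaled corticosteroid) or
#' `"expanded"` (base plus TG, LDL, TC, atrial fibrillation, rheumatoid
#' arthritis, severe mental illness, chronic kidney disease, diabetes).
#'
#' @param data completed cohort data.frame (complete cases are used).
#' @param predictors `"crude"`, `"base"` or `"expanded"`.
#' @param outcome outcome column name.
#' @param reference reference category index.
#' @return list with the `glm` fit, the rows used, the formula and
#'   predictor-set name.
#' @export
fit_outcome_lr <- function(data, predictors = c("base", "crude",
                                                "expanded"),
                           outcome = "outcome_primary", reference = 2L) {
  predictors <- match.arg(predictors)
  vars <- switch(predictors, crude = character(), base = .BASE_VARS,
                 expanded = .EXPANDED_VARS)
  d <- as.data.frame(data)
  if (!is.factor(d$category)) d$category <- factor(d$category)
  ref_label <- levels(d$category)[min(reference,
                                      nlevels(d$category))]
  d$category <- droplevels(d$category)
  orig_levels <- levels(d$category)
  if (!ref_label %in% orig_levels) ref_label <- orig_levels[1]
  d$category <- stats::relevel(d$category, ref = ref_label)
  if ("smoking" %in% vars) {
    d$smoking <- .smoking_factor(d$smoking)
  }
  f <- stats::as.formula(paste(outcome, "~ category",
                               if (length(vars))
                                 paste("+", paste(vars, collapse = "+"))
                               else ""))
  use <- stats::complete.cases(d[, c(outcome, "category", vars),
                                 drop = FALSE])
  fit <- stats::glm(f, family = stats::binomial(), data = d[use, ])
  co <- stats::coef(fit)
  co_slope <- co[setdiff(names(co), "(Intercept)")]
  if (!fit$converged || any(abs(co_slope) > 15, na.rm = TRUE)) {
    worst <- if (length(co_slope) && any(!is.na(co_slope)))
      names(which.max(abs(co_slope))) else "model"
    stop("separation detected in logistic fit (covariate: ", worst, ")",
         call. = FALSE)
  }
  list(fit = fit, rows = which(use), formula = f,
       predictors = predictors, reference = reference,
       outcome = outcome, orig_levels = orig_levels, data = d[use, ])
}

#' Directly standardised marginal risk ratios from a logistic fit
#'
#' For each exposure category k, predicts every patient's outcome
#' probability with their own covariates but exposure set to k, averages
#' to the standardised risk `psi_k`, and reports `RR_k = psi_k /
#' psi_ref`. The 95% CI comes from a nonparametric bootstrap of patients
#' (refitting the regression on each resample).
#'
#' @param lrfit result of [fit_outcome_lr()].
#' @param bootstrap_reps bootstrap replicates (0 disables the CI).
#' @param seed bootstrap seed.
#' @param analysis label for the `analysis` column.
#' @return an `rr_table` (see [aipw_rr()]) with attributes `psi` and
#'   `se_log`.
#' @export
standardize_rr <- function(lrfit, bootstrap_reps = 200L, seed = 1L,
                           analysis = paste0("lr_", lrfit$predictors)) {
  d <- lrfit$data
  fit <- lrfit$fit
  lev <- levels(d$category)          # releveled: reference first
  K <- length(lev)
  X <- stats::model.matrix(fit)
  y <- fit$y
  n <- nrow(X)
  # design matrices with exposure set to each category
  Xk <- lapply(lev, function(l) {
    dk <- d
    dk$category <- factor(l, levels = lev)
    stats::model.matrix(lrfit$formula, dk)
  })
  beta <- stats::coef(fit)
  psi_of <- function(b, idx = NULL) {
    vapply(Xk, function(Xi) {
      if (!is.null(idx)) Xi <- Xi[idx, , drop = FALSE]
      mean(stats::plogis(Xi %*% b))
    }, 0)
  }
  psi <- psi_of(beta)
  rr <- psi / psi[1]

  ci_low <- ci_high <- rep(NA_real_, K)
  se_log <- rep(NA_real_, K)
  if (bootstrap_reps > 0L && nrow(Xk[[1]]) == n) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    bs <- matrix(NA_real_, bootstrap_reps, K)
    for (b in seq_len(bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(suppressWarnings(
        stats::glm.fit(X[idx, , drop = FALSE], y[idx],
                       family = stats::binomial(), start = beta)),
        error = function(e) NULL)
      if (is.null(fb) || !fb$converged) next
      pb <- psi_of(fb$coefficients, idx)
      bs[b, ] <- pb / pb[1]
    }
    qs <- apply(bs, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    ci_low <- qs[1, ]; ci_high <- qs[2, ]
    se_log <- apply(log(pmax(bs, 1e-12)), 2, stats::sd, na.rm = TRUE)
  }
  ci_low[1] <- ci_high[1] <- NA_real_
  se_log[1] <- 0

  # report rows in the original category order (reference back in place)
  natural <- match(lrfit$orig_levels, lev)
  yd <- d[[lrfit$outcome]]
  events <- as.integer(tapply(yd, d$category, sum))
  ns <- as.integer(table(d$category))
  out <- data.frame(analysis = analysis, category = lev,
                    n = ns, events = ifelse(is.na(events), 0L, events),
                    rr = rr, ci_low = ci_low, ci_high = ci_high,
                    reference = lev == lev[1],
                    stringsAsFactors = FALSE)[natural, ]
  rownames(out) <- NULL
  attr(out, "psi") <- psi[natural]
  attr(out, "se_log") <- se_log[natural]
  class(out) <- c("rr_table", "data.frame")
  out
}

#' Pool risk-ratio tables across imputations by Rubin's rules
#'
#' Pools on the log-RR scale: the point estimate is the mean log RR,
#' total variance is within + (1 + 1/m) between, and the 95% CI uses the
#' t distribution with Rubin's degrees of freedom.
#'
#' @param rr_list list of aligned `rr_table`s (same categories, with
#'   `se_log` attributes).
#' @param analysis label for the pooled table.
#' @return pooled `rr_table`.
#' @export
pool_rubin <- function(rr_list, analysis = rr_list[[1]]$analysis[1]) {
  m <- length(rr_list)
  .assert(m >= 2, "need at least 2 imputations to pool")
  cats <- rr_list[[1]]$category
  for (r in rr_list)
    .assert(identical(r$category, cats),
            "integrity error: misaligned categories across imputations")
  logrr <- t(vapply(rr_list, function(r) log(r$rr), numeric(length(cats))))
  selog <- t(vapply(rr_list, function(r) attr(r, "se_log"),
                    numeric(length(cats))))
  qbar <- colMeans(logrr)
  W <- colMeans(selog^2)
  B <- apply(logrr, 2, stats::var)
  Tv <- W + (1 + 1 / m) * B
  ref <- rr_list[[1]]$reference
  ci_low <- ci_high <- rep(NA_real_, length(cats))
  pos <- Tv > 0 & !ref
  nu <- ifelse(B > 0, (m - 1) * (1 + W / ((1 + 1 / m) * B))^2, Inf)
  tq <- stats::qt(0.975, pmax(nu, 1))
  ci_low[pos] <- exp(qbar[pos] - tq[pos] * sqrt(Tv[pos]))
  ci_high[pos] <- exp(qbar[pos] + tq[pos] * sqrt(Tv[pos]))
  out <- rr_list[[1]]
  out$analysis <- analysis
  out$rr <- exp(qbar)
  out$rr[ref] <- 1
  out$ci_low <- ci_low
  out$ci_high <- ci_high
  attr(out, "se_log") <- sqrt(Tv)
  attr(out, "psi") <- NULL
  out
}

#' Logistic-regression risk ratios with imputation and pooling
#'
#' Convenience wrapper for the conventional arm: multiply imputes the
#' missing covariates (when the predictor set needs any and `m >= 2`),
#' fits the logistic outcome model on each completed cohort, directly
#' standardises, and pools by Rubin's rules.
#'
#' @param cohort cohort data.frame.
#' @param predictors `"crude"`, `"base"` or `"expanded"`.
#' @param spec an [imputation_spec()]; its `m` controls the number of
#'   imputations.
#' @param bootstrap_reps per-imputation bootstrap replicates.
#' @param outcome outcome column.
#' @param reference reference category index.
#' @param seed seed for bootstrap CIs.
#' @return an `rr_table`; per-imputation tables in attribute
#'   `imputations` when imputation ran.
#' @export
lr_rr <- function(cohort, predictors = "base", spec = imputation_spec(),
                  bootstrap_reps = 200L, outcome = "outcome_primary",
                  reference = 2L, seed = 1L) {
  vars <- switch(predictors, crude = character(), base = .BASE_VARS,
                 expanded = .EXPANDED_VARS)
  needs <- intersect(spec$variables,
                     c(vars, if ("smoking" %in% vars) "smoking"))
  d <- as.data.frame(cohort)
  has_missing <- length(needs) > 0 &&
    (any(vapply(intersect(needs, setdiff(names(d), "smoking")),
                function(v) anyNA(d[[v]]), TRUE)) ||
       ("smoking" %in% needs && any(d$smoking == "missing")))
  if (!has_missing) {
    fit <- fit_outcome_lr(d, predictors, outcome, reference)
    out <- standardize_rr(fit, bootstrap_reps, seed = seed,
                          analysis = paste0("lr_", predictors))
    return(out)
  }
  comp <- impute_chained(d, spec)
  tabs <- lapply(seq_along(comp), function(i) {
    fit <- fit_outcome_lr(comp[[i]], predictors, outcome, reference)
    standardize_rr(fit, bootstrap_reps, seed = seed + i,
                   analysis = paste0("lr_", predictors))
  })
  out <- pool_rubin(tabs, analysis = paste0("lr_", predictors))
  attr(out, "imputations") <- tabs
  out
}
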