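#' Doubly robust (AIPW) marginal risk ratios from fitted heads
#'
#' The numeric core of the doubly robust estimator. Given outcome
#' predictions `q[i, k] = P(Y=1 | X_i, E=k)` and propensities
#' `g[i, k] = P(E=k | X_i)` (from any source: the sequence encoder, an
#' oracle, or a deliberately mis-specified model), computes the augmented
#' inverse-probability-weighted marginal risk per category
#' \deqn{\hat\psi_k = \frac{1}{n}\sum_i \Big[\frac{1\{E_i=k\}(Y_i -
#'   \hat q_k(X_i))}{\max(\hat g_k(X_i), \epsilon)} + \hat q_k(X_i)\Big]}
#' clipped to (0, 1], risk ratios `RR_k = psi_k / psi_ref`, and percentile
#' bootstrap CIs obtained by resampling patients and re-averaging the
#' influence terms. The estimate is consistent when either set of
#' predictions is correct (double robustness).
#'
#' @param y binary outcome vector.
#' @param exposure integer category per patient (1-based).
#' @param g n-by-K propensity matrix.
#' @param q n-by-K outcome-prediction matrix.
#' @param reference reference category index (no CI is reported for it).
#' @param propensity_clip lower truncation for propensities.
#' @param bootstrap_reps bootstrap replicates (0 disables the CI).
#' @param seed seed for the bootstrap resampling.
#' @param categories optional category labels.
#' @param analysis label stored in the `analysis` column.
#' @return an `rr_table` data.frame: `analysis`, `category`, `n`,
#'   `events`, `rr`, `ci_low`, `ci_high`, `reference`, plus attributes
#'   `psi` and `se_log` (bootstrap SE of log RR).
#' @export
aipw_rr <- function(y, exposure, g, q, reference = 2L,
                    propensity_clip = 0.01, bootstrap_reps = 200L,
                    seed = 1L, categories = NULL, analysis = "dr") {
  n <- length(y)
  K <- ncol(g)
  .assert(nrow(g) == n && nrow(q) == n && ncol(q) == K,
          "g and q must be n-by-K matrices")
  gcl <- pmax(g, propensity_clip)
  resid <- (y - q[cbind(seq_len(n), exposure)])
  contrib <- q
  contrib[cbind(seq_len(n), exposure)] <-
    contrib[cbind(seq_len(n), exposure)] +
    resid / gcl[cbind(seq_len(n), exposure)]
  psi <- pmin(pmax(colMeans(contrib), 0), 1)
  .assert(psi[reference] > 0,
          "estimation failure: reference-category risk is zero")
  rr <- psi / psi[reference]

  ci_low <- ci_high <- rep(NA_real_, K)
  se_log <- rep(NA_real_, K)
  if (bootstrap_reps > 0L) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    bs <- matrix(NA_real_, bootstrap_reps, K)
    for (b in seq_len(bootstrap_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      pb <- pmin(pmax(colMeans(contrib[idx, , drop = FALSE]), 0), 1)
      if (pb[reference] > 0) bs[b, ] <- pb / pb[reference]
    }
    qs <- apply(bs, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE)
    ci_low <- qs[1, ]; ci_high <- qs[2, ]
    se_log <- apply(log(pmax(bs, 1e-12)), 2, stats::sd, na.rm = TRUE)
  }
  ci_low[reference] <- ci_high[reference] <- NA_real_
  se_log[reference] <- 0
  if (is.null(categories)) categories <- paste0("cat", seq_len(K))
  out <- data.frame(analysis = analysis, category = categories,
                    n = as.integer(tabulate(exposure, nbins = K)),
                    events = as.integer(rowsum(y, exposure)[, 1][
                      as.character(seq_len(K))]),
                    rr = rr, ci_low = ci_low, ci_high = ci_high,
                    reference = seq_len(K) == reference,
                    stringsAsFactors = FALSE)
  out$events[is.na(out$events)] <- 0L
  attr(out, "psi") <- psi
  attr(out, "se_log") <- se_log
  class(out) <- c("rr_table", "data.frame")
  out
}

#' Fit the doubly robust sequence model
#'
#' Trains the shared sequence encoder (see [encoder_config()]) on the
#' cohort's pre-baseline token streams with three objectives — 6-way
#' exposure propensity, per-category outcome prediction, and a
#' masked-token auxiliary loss — and combines the two heads into
#' doubly robust (AIPW) marginal risk ratios per SBP category with
#' bootstrap confidence intervals.
#'
#' @param cohort a cohort data.frame from [build_cohort()].
#' @param events the raw event table (pre-baseline rows are tokenised).
#' @param config an [encoder_config()].
#' @param outcome name of the outcome column (default primary composite).
#' @param reference reference category index.
#' @param crossfit use 2-fold cross-fitting (default): each half of the
#'   cohort is scored by an encoder trained on the other half, removing
#'   own-sample correlation between the fitted heads and the residuals
#'   that enter the AIPW combination.
#' @return an object of class `drseq` with components `rr` (an
#'   `rr_table`), `propensity` and `outcome_pred` matrices, `loss`
#'   (per-epoch training loss), `model`, `sequences` metadata, and the
#'   crude per-category risks.
#' @seealso [aipw_rr()] for the estimator given arbitrary heads;
#'   [predict.drseq()], [summary.drseq()], [plot.drseq()].
#' @export
drseq <- function(cohort, events, config = encoder_config(),
                  outcome = "outcome_primary", reference = 2L,
                  crossfit = TRUE) {
  .assert(inherits(cohort, "data.frame") && nrow(cohort) > 0,
          "cohort must be a nonempty data.frame")
  y <- cohort[[outcome]]
  .assert(all(y %in% 0:1), "outcome must be binary")
  exposure <- as.integer(cohort$category)
  cats <- levels(cohort$category)
  K <- length(cats)
  seqs <- build_sequences(cohort, events, config$max_sequence_length)
  n <- nrow(cohort)
  if (crossfit && n >= 200L) {
    old <- .Random.seed_save()
    set.seed(config$seed + 17L)
    fold <- sample(rep(1:2, length.out = n))
    .Random.seed_restore(old)
    g <- matrix(NA_real_, n, K)
    q <- g
    model <- NULL
    loss <- 0
    for (f in 1:2) {
      tr_idx <- which(fold != f)
      te_idx <- which(fold == f)
      seqs_tr <- .subset_sequences(seqs, tr_idx)
      m_f <- .enc_train(seqs_tr, exposure[tr_idx], y[tr_idx], config,
                        n_cat = K, cat_labels = cats)
      p_f <- .enc_predict(m_f, .subset_sequences(seqs, te_idx))
      g[te_idx, ] <- p_f$g
      q[te_idx, ] <- p_f$q
      loss <- loss + m_f$loss / 2
      model <- m_f    # keep the last fold's encoder for inspection
    }
    pred <- list(g = g, q = q)
    model$loss <- loss
  } else {
    model <- .enc_train(seqs, exposure, y, config, n_cat = K,
                        cat_labels = cats)
    pred <- .enc_predict(model, seqs)
  }
  rr <- aipw_rr(y, exposure, pred$g, pred$q, reference = reference,
                propensity_clip = config$propensity_clip,
                bootstrap_reps = config$bootstrap_reps,
                seed = config$seed + 1L, categories = cats,
                analysis = "dr_sequence")
  crude_risk <- as.numeric(tapply(y, exposure, mean))
  structure(list(rr = rr, propensity = pred$g, outcome_pred = pred$q,
                 loss = model$loss, model = model, config = config,
                 vocab = seqs$vocab,
                 reference = reference, categories = cats,
                 y = y, exposure = exposure,
                 crude_rr = crude_risk / crude_risk[reference],
                 n = nrow(cohort), outcome = outcome,
                 call = match.call()),
            class = "drseq")
}

#' @export
print.drseq <- function(x, ...) {
  cat("Doubly robust sequence-model risk ratios\n")
  cat("  n =", x$n, " events =", sum(x$y), " outcome:", x$outcome, "\n\n")
  print(x$rr)
  invisible(x)
}

#' @export
summary.drseq <- function(object, ...) {
  structure(list(rr = object$rr, loss = object$loss,
                 crude_rr = object$crude_rr, n = object$n,
                 events = sum(object$y), outcome = object$outcome,
                 propensity_range = range(object$propensity),
                 categories = object$categories),
            class = "summary.drseq")
}

#' @export
print.summary.drseq <- function(x, ...) {
  cat("Doubly robust sequence-model fit\n")
  cat("  n =", x$n, " events =", x$events, " outcome:", x$outcome, "\n")
  cat("  training loss by epoch:",
      paste(signif(x$loss, 4), collapse = " "), "\n")
  cat("  propensity range: [", signif(x$propensity_range[1], 3), ",",
      signif(x$propensity_range[2], 3), "]\n\n")
  print(x$rr)
  cat("\nCrude risk ratios:",
      paste(sprintf("%s %.3f", x$categories, x$crude_rr),
            collapse = ", "), "\n")
  invisible(x)
}

#' Predictions from a fitted doubly robust sequence model
#'
#' @param object a `drseq` fit.
#' @param newdata optional list with `cohort` and `events`; defaults to
#'   the training cohort's stored predictions.
#' @param type `"propensity"` for the K-column propensity matrix or
#'   `"outcome"` for per-category outcome probabilities.
#' @param ... unused.
#' @return a numeric matrix with one row per patient.
#' @export
predict.drseq <- function(object, newdata = NULL,
                          type = c("propensity", "outcome"), ...) {
  type <- match.arg(type)
  if (is.null(newdata))
    return(if (type == "propensity") object$propensity
           else object$outcome_pred)
  seqs <- build_sequences(newdata$cohort, newdata$events,
                          object$config$max_sequence_length,
                          vocab = object$vocab)
  pred <- .enc_predict(object$model, seqs)
  if (type == "propensity") pred$g else pred$q
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Risk-ratio table from a fitted model
#'
#' @param object a fitted model (`drseq`) or object carrying an
#'   `rr_table`.
#' @param ... passed to methods.
#' @return an `rr_table` data.frame.
#' @export
risk_ratio <- function(object, ...) UseMethod("risk_ratio")

#' @export
risk_ratio.drseq <- function(object, ...) object$rr

#' @export
risk_ratio.rr_table <- function(object, ...) object

#' @export
print.rr_table <- function(x, digits = 2, ...) {
  fmt <- ifelse(x$reference, "1.00 (reference)",
                sprintf(paste0("%.", digits, "f (%.", digits, "f to %.",
                               digits, "f)"), x$rr, x$ci_low, x$ci_high))
  fmt[!x$reference & is.na(x$ci_low)] <-
    sprintf(paste0("%.", digits, "f"), x$rr[!x$reference & is.na(x$ci_low)])
  df <- data.frame(analysis = x$analysis, category = x$category,
                   `events/n` = paste0(x$events, "/", x$n),
                   `RR (95% CI)` = fmt, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Forest plot of risk-ratio estimates
#'
#' Draws point estimates and 95% CIs on a log scale, one row per
#' category (base graphics).
#'
#' @param x a `drseq` fit or an `rr_table`.
#' @param main plot title.
#' @param ... passed to [graphics::plot()].
#' @export
plot.drseq <- function(x, main = "Doubly robust risk ratios", ...) {
  plot(risk_ratio(x), main = main, ...)
}

#' @export
plot.rr_table <- function(x, main = "Risk ratios", ...) {
  k <- nrow(x)
  ylim <- c(0.5, k + 0.5)
  xr <- range(c(x$rr, x$ci_low, x$ci_high), na.rm = TRUE)
  xr <- c(min(xr[1], 0.8), max(xr[2], 1.25))
  graphics::plot(x$rr, rev(seq_len(k)), log = "x", xlim = xr, ylim = ylim,
                 pch = 15, xlab = "Risk ratio (log scale)", ylab = "",
                 yaxt = "n", main = main, ...)
  graphics::axis(2, at = rev(seq_len(k)), labels = x$category, las = 1)
  graphics::segments(x$ci_low, rev(seq_len(k)), x$ci_high,
                     rev(seq_len(k)))
  graphics::abline(v = 1, lty = 2, col = "grey50")
  invisible(x)
}
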