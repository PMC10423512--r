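# The sequence encoder: token + age embeddings, multi-head attention
# pooling, dense layers, and three heads (6-way propensity softmax,
# per-category outcome sigmoids, masked-token softmax). Training is plain
# reverse-mode differentiation written out by hand with Adam updates; the
# gradient code is validated against numerical differentiation in the
# test suite.

.rowmax <- function(x) {
  m <- x[, 1]
  for (j in seq_len(ncol(x))[-1]) m <- pmax(m, x[, j])
  m
}

.softmax_rows <- function(x) {
  e <- exp(x - .rowmax(x))
  e / rowSums(e)
}

.enc_init <- function(cfg, n_vocab, n_age, n_cat, y_mean, cat_share) {
  d <- cfg$embedding_width
  H <- cfg$n_attention_heads
  in1 <- H * d + 1L
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  W <- vector("list", cfg$n_layers)
  b <- vector("list", cfg$n_layers)
  for (l in seq_len(cfg$n_layers)) {
    nin <- if (l == 1L) in1 else d
    W[[l]] <- rn(nin, d, sqrt(2 / nin))
    b[[l]] <- rep(0, d)
  }
  list(E = rn(n_vocab, d, 0.05), A = rn(n_age, d, 0.05),
       Q = rn(d, H, 0.2), W = W, b = b,
       Wp = rn(d, n_cat, 0.05), bp = log(pmax(cat_share, 1e-6)),
       Wo = rn(d, n_cat, 0.05),
       bo = rep(stats::qlogis(min(max(y_mean, 1e-4), 1 - 1e-4)), n_cat),
       Wm = rn(d, n_vocab, 0.05), bm = rep(0, n_vocab))
}

# forward pass over one flattened batch
# bt: tokens, age, p (patient index 1..P), P, loglen, exposure, y
.enc_forward <- function(params, bt, cfg) {
  d <- cfg$embedding_width
  H <- cfg$n_attention_heads
  P <- bt$P
  Xe <- params$E[bt$tokens, , drop = FALSE] +
    params$A[bt$age, , drop = FALSE]
  alpha <- matrix(0, length(bt$tokens), H)
  pool <- matrix(0, P, H * d)
  for (h in seq_len(H)) {
    s <- as.numeric(Xe %*% params$Q[, h]) / sqrt(d)
    if (max(abs(s)) < 25) {     # shift-invariant; stabilise only if needed
      e <- exp(s)
    } else {
      mx <- as.numeric(tapply(s, bt$p, max))
      e <- exp(s - mx[bt$p])
    }
    Z <- rowsum(e, bt$p)
    a <- as.numeric(e / Z[bt$p])
    alpha[, h] <- a
    pool[, ((h - 1L) * d + 1L):(h * d)] <- rowsum(a * Xe, bt$p)
  }
  feat <- cbind(pool, bt$loglen)
  zs <- vector("list", cfg$n_layers + 1L)
  pres <- vector("list", cfg$n_layers)
  zs[[1]] <- feat
  for (l in seq_len(cfg$n_layers)) {
    pre <- sweep(zs[[l]] %*% params$W[[l]], 2, params$b[[l]], `+`)
    pres[[l]] <- pre
    zs[[l + 1L]] <- pmax(pre, 0)
  }
  z <- zs[[cfg$n_layers + 1L]]
  lp <- sweep(z %*% params$Wp, 2, params$bp, `+`)
  lo <- sweep(z %*% params$Wo, 2, params$bo, `+`)
  list(Xe = Xe, alpha = alpha, zs = zs, pres = pres, z = z,
       ghat = .softmax_rows(lp), q = stats::plogis(lo))
}

# loss and gradients for one batch; mask_sel selects masked token rows
# (their input ids are replaced by [MASK]; original ids are the labels)
.enc_grads <- function(params, bt, cfg, mask_sel) {
  d <- cfg$embedding_width
  H <- cfg$n_attention_heads
  P <- bt$P
  K <- ncol(params$Wp)
  V <- nrow(params$E)
  labels <- bt$tokens[mask_sel]
  tok_in <- bt$tokens
  tok_in[mask_sel] <- 2L  # [MASK]
  btm <- bt; btm$tokens <- tok_in
  fw <- .enc_forward(params, btm, cfg)
  z <- fw$z

  iKe <- cbind(seq_len(P), bt$exposure)
  ge <- fw$ghat[iKe]
  loss_prop <- -mean(log(pmax(ge, 1e-12)))
  qe <- fw$q[iKe]
  loss_out <- -mean(bt$y * log(pmax(qe, 1e-12)) +
                      (1 - bt$y) * log(pmax(1 - qe, 1e-12)))
  w_o <- if (is.null(cfg$outcome_weight)) 1 else cfg$outcome_weight

  dlp <- fw$ghat
  dlp[iKe] <- dlp[iKe] - 1
  dlp <- dlp / P
  dlo <- matrix(0, P, K)
  dlo[iKe] <- w_o * (qe - bt$y) / P

  n_m <- length(labels)
  loss_mask <- 0
  dlm <- NULL
  if (n_m > 0L) {
    # masked-token softmax computed once per patient with masked tokens
    mp <- bt$p[mask_sel]
    up <- sort(unique(mp))
    nu <- length(up)
    mpi <- match(mp, up)
    lmu <- sweep(z[up, , drop = FALSE] %*% params$Wm, 2, params$bm, `+`)
    smu <- .softmax_rows(lmu)
    loss_mask <- -mean(log(pmax(smu[cbind(mpi, labels)], 1e-12)))
    cnt <- tabulate(mpi, nu)
    sub <- matrix(tabulate(mpi + (labels - 1L) * nu, nu * V), nu, V)
    dlmu <- (smu * cnt - sub) * cfg$mask_weight / n_m
    dlm <- matrix(0, P, V)
    dlm[up, ] <- dlmu
  }

  dz <- dlp %*% t(params$Wp) + dlo %*% t(params$Wo)
  g <- list(Wp = crossprod(z, dlp), bp = colSums(dlp),
            Wo = crossprod(z, dlo), bo = colSums(dlo),
            Wm = matrix(0, d, V), bm = rep(0, V))
  if (!is.null(dlm)) {
    dz <- dz + dlm %*% t(params$Wm)
    g$Wm <- crossprod(z, dlm)
    g$bm <- colSums(dlm)
  }

  g$W <- vector("list", cfg$n_layers)
  g$b <- vector("list", cfg$n_layers)
  for (l in rev(seq_len(cfg$n_layers))) {
    dpre <- dz * (fw$pres[[l]] > 0)
    g$W[[l]] <- crossprod(fw$zs[[l]], dpre)
    g$b[[l]] <- colSums(dpre)
    dz <- dpre %*% t(params$W[[l]])
  }
  dpool <- dz[, seq_len(H * d), drop = FALSE]

  Xe <- fw$Xe
  dXe <- matrix(0, nrow(Xe), d)
  g$Q <- matrix(0, d, H)
  for (h in seq_len(H)) {
    dPh <- dpool[, ((h - 1L) * d + 1L):(h * d), drop = FALSE]
    dPh_tok <- dPh[bt$p, , drop = FALSE]
    a <- fw$alpha[, h]
    dalpha <- rowSums(Xe * dPh_tok)
    Sp <- rowsum(a * dalpha, bt$p)
    ds <- a * (dalpha - Sp[bt$p])
    dXe <- dXe + a * dPh_tok + tcrossprod(ds, params$Q[, h]) / sqrt(d)
    g$Q[, h] <- crossprod(Xe, ds) / sqrt(d)
  }
  gEa <- rowsum(dXe, tok_in)
  g$E <- matrix(0, V, d)
  g$E[as.integer(rownames(gEa)), ] <- gEa
  gAa <- rowsum(dXe, bt$age)
  g$A <- matrix(0, nrow(params$A), d)
  g$A[as.integer(rownames(gAa)), ] <- gAa

  list(loss = loss_prop + w_o * loss_out + cfg$mask_weight * loss_mask,
       loss_prop = loss_prop, loss_out = loss_out, loss_mask = loss_mask,
       grads = g)
}

.adam_new <- function(params) {
  zero <- function(x) if (is.list(x)) lapply(x, zero) else x * 0
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

# decoupled weight decay applies to dense and head weight matrices, not
# to embeddings or biases
.WD_PARAMS <- c("Q", "W", "Wp", "Wo", "Wm")

.adam_step <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                       eps = 1e-8, wd = 0) {
  state$t <- state$t + 1L
  upd <- function(p, g, m, v, decay) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^state$t)
    vh <- v / (1 - b2^state$t)
    list(p = p - lr * (mh / (sqrt(vh) + eps) + decay * p), m = m, v = v)
  }
  for (nm in names(params)) {
    decay <- if (nm %in% .WD_PARAMS) wd else 0
    if (is.list(params[[nm]])) {
      for (l in seq_along(params[[nm]])) {
        r <- upd(params[[nm]][[l]], grads[[nm]][[l]],
                 state$m[[nm]][[l]], state$v[[nm]][[l]], decay)
        params[[nm]][[l]] <- r$p
        state$m[[nm]][[l]] <- r$m
        state$v[[nm]][[l]] <- r$v
      }
    } else {
      r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]],
               decay)
      params[[nm]] <- r$p
      state$m[[nm]] <- r$m
      state$v[[nm]] <- r$v
    }
  }
  list(params = params, state = state)
}

# slice a batch of patients out of flattened sequences
.enc_batch <- function(seqs, sel, loglen, exposure, y) {
  starts <- attr(seqs, "starts")
  len <- seqs$lengths[sel]
  idx <- sequence(len) + rep(starts[sel], len)
  list(tokens = seqs$tokens[idx], age = seqs$age_ids[idx],
       p = rep(seq_along(sel), len), P = length(sel),
       loglen = loglen[sel], exposure = exposure[sel], y = y[sel],
       token_idx = idx)
}

.with_starts <- function(seqs) {
  n <- length(seqs$lengths)
  attr(seqs, "starts") <- cumsum(c(0L, seqs$lengths[-n]))
  seqs
}

# train the encoder; returns params, loss history and normalisation info
.enc_train <- function(seqs, exposure, y, cfg, n_cat = max(exposure),
                       cat_labels = as.character(seq_len(n_cat))) {
  n <- length(seqs$lengths)
  .assert(length(unique(exposure)) >= 2L,
          "need at least 2 exposure categories")
  K <- n_cat
  counts <- tabulate(exposure, nbins = K)
  zero_cat <- which(counts == 0L)
  .assert(length(zero_cat) == 0L, "category %s has zero members",
          paste(cat_labels[zero_cat], collapse = ","))
  seqs <- .with_starts(seqs)
  ll_raw <- log1p(seqs$lengths - seqs$n_static)
  ll_c <- mean(ll_raw); ll_s <- max(stats::sd(ll_raw), 1e-8)
  loglen <- (ll_raw - ll_c) / ll_s

  set.seed(cfg$seed)
  params <- .enc_init(cfg, length(seqs$vocab), .N_AGE_BUCKETS, K,
                      mean(y), counts / n)
  state <- .adam_new(params)
  epoch_loss <- numeric(cfg$epochs)
  is_static <- sequence(seqs$lengths) <= seqs$n_static
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    nb <- ceiling(n / cfg$batch_size)
    tot <- 0
    # cosine learning-rate decay over epochs (floor at 10% of peak)
    lr_ep <- cfg$learning_rate *
      (0.1 + 0.9 * 0.5 * (1 + cos(pi * (ep - 1) / max(cfg$epochs - 1, 1))))
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size, n)]
      bt <- .enc_batch(seqs, sel, loglen, exposure, y)
      hist_tok <- !is_static[bt$token_idx]
      mask_sel <- hist_tok & stats::runif(length(bt$tokens)) < cfg$mask_fraction
      r <- .enc_grads(params, bt, cfg, mask_sel)
      st <- .adam_step(params, r$grads, state, lr_ep,
                       wd = if (is.null(cfg$weight_decay)) 0
                            else cfg$weight_decay)
      params <- st$params
      state <- st$state
      tot <- tot + r$loss * bt$P
    }
    epoch_loss[ep] <- tot / n
  }
  list(params = params, loss = epoch_loss, cfg = cfg,
       loglen_center = ll_c, loglen_scale = ll_s, n_cat = K)
}

# propensity and outcome predictions for all patients
.enc_predict <- function(model, seqs, chunk = 2048L) {
  seqs <- .with_starts(seqs)
  n <- length(seqs$lengths)
  ll <- (log1p(seqs$lengths - seqs$n_static) - model$loglen_center) /
    model$loglen_scale
  K <- model$n_cat
  gh <- matrix(0, n, K)
  qh <- matrix(0, n, K)
  for (start in seq(1L, n, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n)
    bt <- .enc_batch(seqs, sel, ll, rep(1L, n), rep(0, n))
    fw <- .enc_forward(model$params, bt, model$cfg)
    gh[sel, ] <- fw$ghat
    qh[sel, ] <- fw$q
  }
  list(g = gh, q = qh)
}
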