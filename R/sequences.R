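# Tokenisation of pre-baseline medical history for the sequence encoder.
# Each patient's sequence starts with static tokens (sex, smoking status,
# 5-year age band at baseline, registration-span band) followed by their
# diagnosis/medication codes in date order, truncated to the newest
# `max_sequence_length` tokens. Out-of-vocabulary codes map to "[UNK]".

.N_AGE_BUCKETS <- 32L  # 5-year bands from age 0 upwards

.age_bucket <- function(age) pmin(pmax(age %/% 5L, 0L) + 1L, .N_AGE_BUCKETS)

#' Build a token vocabulary from an event table
#'
#' Deterministic: the vocabulary is the sorted set of distinct codes plus
#' reserved special and static tokens.
#'
#' @param codes character vector of event codes.
#' @return character vector; attribute `n_special` counts reserved slots.
#' @export
build_vocabulary <- function(codes) {
  static <- c(paste0("SEX:", .SEX_LEVELS),
              paste0("SMOK:", .SMOKING_LEVELS),
              paste0("SPAN:", 0:15),
              paste0("AGE:", seq_len(.N_AGE_BUCKETS)))
  c("[UNK]", "[MASK]", static, sort(unique(codes)))
}

#' Build patient token sequences for the encoder
#'
#' @param cohort a cohort data.frame (see [build_cohort()]).
#' @param events full event table; only events dated on/before each
#'   patient's baseline enter the sequence.
#' @param max_sequence_length truncation limit; when a history is longer,
#'   the oldest events are dropped and the newest retained.
#' @param vocab optional fixed vocabulary (from [build_vocabulary()]); by
#'   default built from the events supplied.
#' @return object of class `patient_sequences`: list with `tokens` and
#'   `age_ids` (integer vectors, flattened), `lengths`, `patient_id`,
#'   `vocab`, `n_static`.
#' @export
build_sequences <- function(cohort, events,
                            max_sequence_length = 256L,
                            vocab = NULL) {
  n <- nrow(cohort)
  pid <- match(events$patient_id, cohort$patient_id)
  keep <- !is.na(pid) & events$date <= cohort$baseline_date[pid]
  pid <- pid[keep]
  code <- events$code[keep]
  dt <- as.integer(events$date[keep])
  if (is.null(vocab)) vocab <- build_vocabulary(code)
  o <- order(pid, dt, code)
  pid <- pid[o]; code <- code[o]; dt <- dt[o]

  tok <- match(code, vocab)
  tok[is.na(tok)] <- 1L  # [UNK]
  byear <- as.integer(format(cohort$baseline_date, "%Y"))
  eyear <- as.POSIXlt(as.Date(dt, origin = "1970-01-01"))$year + 1900L
  age_ev <- .age_bucket(cohort$age[pid] - (byear[pid] - eyear))

  # truncate: keep the newest max_len - n_static history tokens
  n_static <- 4L
  limit <- max_sequence_length - n_static
  .assert(limit > 0L, "max_sequence_length too small for static tokens")
  cnt <- tabulate(pid, nbins = n)
  pos <- sequence(cnt)            # 1..cnt within patient (date order)
  keep2 <- pos > rep(cnt - limit, cnt)
  pid <- pid[keep2]; tok <- tok[keep2]; age_ev <- age_ev[keep2]
  cnt <- tabulate(pid, nbins = n)

  span_days <- if (!is.null(cohort$registration_start))
    as.numeric(cohort$baseline_date - cohort$registration_start)
  else rep(0, n)
  span_years <- pmin(15L, pmax(0L, as.integer(span_days %/% .DAYS_YEAR)))
  smoking <- ifelse(cohort$smoking %in% .SMOKING_LEVELS,
                    cohort$smoking, "missing")
  static_tok <- rbind(match(paste0("SEX:", cohort$sex), vocab),
                      match(paste0("SMOK:", smoking), vocab),
                      match(paste0("SPAN:", span_years), vocab),
                      match(paste0("AGE:", .age_bucket(cohort$age)), vocab))
  static_tok[is.na(static_tok)] <- 1L
  # age band at baseline rides on the age embedding of every static token
  static_age <- matrix(rep(.age_bucket(cohort$age), each = 4L), nrow = 4L)

  # interleave static tokens before each patient's history
  lengths <- cnt + n_static
  out_pid <- rep(seq_len(n), lengths)
  tokens <- integer(sum(lengths))
  age_ids <- integer(sum(lengths))
  starts <- cumsum(c(0L, lengths[-n])) # 0-based starts
  st_idx <- rep(starts, each = n_static) + rep(1:n_static, n)
  tokens[st_idx] <- as.integer(static_tok)
  age_ids[st_idx] <- as.integer(static_age)
  hist_idx <- setdiff(seq_len(sum(lengths)), st_idx)
  tokens[hist_idx] <- tok
  age_ids[hist_idx] <- age_ev

  structure(list(tokens = tokens, age_ids = age_ids,
                 patient_index = out_pid, lengths = lengths,
                 patient_id = cohort$patient_id, vocab = vocab,
                 n_static = n_static),
            class = "patient_sequences")
}

#' @export
print.patient_sequences <- function(x, ...) {
  cat("Patient token sequences:", length(x$lengths), "patients,",
      length(x$tokens), "tokens, vocabulary size", length(x$vocab), "\n")
  cat("  sequence length: median", stats::median(x$lengths), "max",
      max(x$lengths), "\n")
  invisible(x)
}

# restrict flattened sequences to a subset of patients (keeps vocab)
.subset_sequences <- function(seqs, idx) {
  n <- length(seqs$lengths)
  starts <- cumsum(c(0L, seqs$lengths[-n]))
  len <- seqs$lengths[idx]
  rows <- sequence(len) + rep(starts[idx], len)
  structure(list(tokens = seqs$tokens[rows], age_ids = seqs$age_ids[rows],
                 patient_index = rep(seq_along(idx), len), lengths = len,
                 patient_id = seqs$patient_id[idx], vocab = seqs$vocab,
                 n_static = seqs$n_static),
            class = "patient_sequences")
}

# materialise one patient's token vector (mainly for tests/inspection)
tokens_of <- function(seqs, i) {
  idx <- which(seqs$patient_index == i)
  seqs$vocab[seqs$tokens[idx]]
}
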