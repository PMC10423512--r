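# The five sensitivity analyses, Table-1-style descriptives, and forest
# tables.

.SENSITIVITY_NAMES <- c("no_antihypertensive", "post_2001",
                        "exclude_12m_events", "exclude_24m_events",
                        "smokers_only")

#' Apply a named sensitivity filter to the cohort
#'
#' The five analyses are: `no_antihypertensive` (patients with no
#' antihypertensive use during the follow-up period), `post_2001`
#' (baseline on/after 1 January 2001), `exclude_12m_events` /
#' `exclude_24m_events` (exclude patients whose first cardiovascular
#' event falls in the first 12/24 months *of the follow-up period*, i.e.
#' in `[baseline + 365, baseline + 730)` / `[baseline + 365,
#' baseline + 1095)` days), and `smokers_only` (current and former
#' smokers).
#'
#' @param cohort cohort data.frame.
#' @param name one of the five sensitivity analysis names.
#' @param config a [run_config()] (for window arithmetic).
#' @return the filtered cohort (possibly with a warning when empty).
#' @export
sensitivity_filter <- function(cohort, name, config = run_config()) {
  .assert(length(name) == 1L && name %in% .SENSITIVITY_NAMES,
          "unknown sensitivity analysis '%s' (use one of: %s)",
          paste(name, collapse = ","),
          paste(.SENSITIVITY_NAMES, collapse = ", "))
  fs <- config$followup_start_days
  keep <- switch(
    name,
    no_antihypertensive = cohort$antihypertensive_fu == 0L,
    post_2001 = cohort$baseline_date >= as.Date("2001-01-01"),
    exclude_12m_events = !(!is.na(cohort$first_event_date) &
      cohort$first_event_date >= cohort$baseline_date + fs &
      cohort$first_event_date < cohort$baseline_date + fs + 365L),
    exclude_24m_events = !(!is.na(cohort$first_event_date) &
      cohort$first_event_date >= cohort$baseline_date + fs &
      cohort$first_event_date < cohort$baseline_date + fs + 730L),
    smokers_only = cohort$smoking %in% c("current", "former")
  )
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("sensitivity analysis '", name, "' leaves an empty cohort",
            call. = FALSE)
  rownames(out) <- NULL
  out
}

.q_iqr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(NA_real_, NA_real_, NA_real_))
  stats::quantile(x, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
}

.fmt_iqr <- function(q, digits = 1) {
  if (anyNA(q)) return("")
  sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
          q[1], q[2], q[3])
}

#' Cohort descriptives by exposure category
#'
#' A Table-1-style summary: per category the patient count and
#' percentage of the cohort; median (IQR, 25th/75th percentile with
#' linear interpolation) of follow-up years, age, BMI and lipids; and
#' percentages of women, smoking status (reported both as a share of the
#' category and as a share of patients with known smoking status),
#' baseline diseases and baseline medications. Percentages are reported
#' to one decimal.
#'
#' @param cohort nonempty cohort data.frame.
#' @return object of class `cohort_descriptives`: list with the numeric
#'   `stats` (one element per summary), the formatted `table`
#'   (data.frame, categories in columns), and `n`.
#' @export
describe_cohort <- function(cohort) {
  .assert(nrow(cohort) > 0, "cohort is empty")
  cats <- levels(cohort$category)
  by_cat <- split(seq_len(nrow(cohort)), cohort$category)
  n_cat <- vapply(by_cat, length, 0L)
  n <- nrow(cohort)
  pct <- function(x) round(100 * x, 1)

  num_rows <- list(followup_years = 1, age = 1, bmi = 1, tc = 1, tg = 1,
                   ldl = 1)
  tab <- data.frame(row.names = cats)
  stats_out <- list(n = n_cat, pct = pct(n_cat / n))
  tab_rows <- list(`No. (%)` = sprintf("%d (%.1f)", n_cat,
                                       pct(n_cat / n)))
  for (v in names(num_rows)) {
    qs <- lapply(by_cat, function(i) .q_iqr(cohort[[v]][i]))
    stats_out[[v]] <- do.call(rbind, qs)
    tab_rows[[v]] <- vapply(qs, .fmt_iqr, "")
  }
  prop_row <- function(flag) {
    cnt <- vapply(by_cat, function(i) sum(flag[i], na.rm = TRUE), 0)
    list(count = cnt, pct = pct(cnt / n_cat))
  }
  binaries <- c(women = "sex", ihd = "flag_ihd", ckd = "flag_ckd",
                diabetes = "flag_diabetes", smi = "flag_smi",
                af = "flag_af", antihypertensive = "antihypertensive",
                ics = "ics", laba = "laba",
                beta_blocker = "beta_blocker")
  for (nm in names(binaries)) {
    col <- binaries[[nm]]
    flag <- if (col == "sex") cohort$sex == "female" else cohort[[col]] == 1L
    pr <- prop_row(flag)
    stats_out[[nm]] <- pr
    tab_rows[[nm]] <- sprintf("%d (%.1f)", pr$count, pr$pct)
  }
  known_smoking <- cohort$smoking %in% c("current", "former", "never")
  n_known <- vapply(by_cat, function(i) sum(known_smoking[i]), 0)
  for (s in c("current", "former", "never")) {
    cnt <- vapply(by_cat, function(i) sum(cohort$smoking[i] == s), 0)
    stats_out[[paste0("smoking_", s)]] <-
      list(count = cnt, pct_of_category = pct(cnt / n_cat),
           pct_of_known = pct(cnt / pmax(n_known, 1)))
    tab_rows[[paste0("smoker_", s)]] <-
      sprintf("%d (%.1f; %.1f of known)", cnt, pct(cnt / n_cat),
              pct(cnt / pmax(n_known, 1)))
  }
  tab <- as.data.frame(do.call(rbind, tab_rows), stringsAsFactors = FALSE)
  names(tab) <- cats
  structure(list(stats = stats_out, table = tab, n = n,
                 categories = cats),
            class = "cohort_descriptives")
}

#' @export
print.cohort_descriptives <- function(x, ...) {
  cat("Cohort descriptives by SBP category (n =", x$n, ")\n")
  print(x$table)
  invisible(x)
}

#' Forest-table report of risk-ratio estimates
#'
#' Combines one or more `rr_table`s into a single report with rendered
#' estimate strings (`"1.16 (1.10 to 1.22)"`; the reference row as
#' `"1.00 (reference)"` with empty CI fields) and log-scale plotting
#' coordinates.
#'
#' @param rr_tables an `rr_table` or list of them.
#' @param labels optional analysis labels (recycled per table).
#' @return data.frame with columns `analysis`, `category`, `events_n`,
#'   `rr`, `ci_low`, `ci_high`, `estimate`, `log_rr`, `log_ci_low`,
#'   `log_ci_high`, `reference`.
#' @export
forest_table <- function(rr_tables, labels = NULL) {
  if (inherits(rr_tables, "rr_table")) rr_tables <- list(rr_tables)
  if (length(rr_tables) == 0L)
    return(data.frame(analysis = character(), category = character(),
                      events_n = character(), rr = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      estimate = character(), log_rr = numeric(),
                      log_ci_low = numeric(), log_ci_high = numeric(),
                      reference = logical(), stringsAsFactors = FALSE))
  rows <- lapply(seq_along(rr_tables), function(i) {
    r <- rr_tables[[i]]
    lab <- if (!is.null(labels)) labels[[i]] else r$analysis
    est <- ifelse(r$reference, "1.00 (reference)",
                  sprintf("%.2f (%.2f to %.2f)", r$rr, r$ci_low,
                          r$ci_high))
    est[!r$reference & is.na(r$ci_low)] <-
      sprintf("%.2f", r$rr[!r$reference & is.na(r$ci_low)])
    data.frame(analysis = lab, category = r$category,
               events_n = paste0(r$events, "/", r$n),
               rr = r$rr,
               ci_low = ifelse(r$reference, NA_real_, r$ci_low),
               ci_high = ifelse(r$reference, NA_real_, r$ci_high),
               estimate = est, log_rr = log(r$rr),
               log_ci_low = log(ifelse(r$reference, NA_real_, r$ci_low)),
               log_ci_high = log(ifelse(r$reference, NA_real_,
                                        r$ci_high)),
               reference = r$reference, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
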