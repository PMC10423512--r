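# Table schemas, delimited-text readers/writers and the code-list table.
# All files are comma-separated UTF-8 with a header row; missing values are
# empty fields; dates are ISO-8601.

.SEX_LEVELS <- c("female", "male")
.SMOKING_LEVELS <- c("current", "former", "never", "missing")
.EVENT_KINDS <- c("diagnosis", "medication")
.EVENT_SOURCES <- c("primary_care", "secondary_care", "mortality")
.MEASUREMENT_KINDS <- c("sbp", "bmi", "tc", "tg", "ldl")
.DATE_MIN <- as.Date("1900-01-01")
.DATE_MAX <- as.Date("2020-12-31")

#' Default code-list table
#'
#' Maps the synthetic code vocabulary onto endpoint and covariate classes:
#' the cohort-defining COPD code, cardiovascular endpoint codes (IHD,
#' heart failure, stroke, cardiovascular death), chronic-disease codes
#' (atrial fibrillation, chronic kidney disease, diabetes, rheumatoid
#' arthritis, severe mental illness), and medication codes
#' (antihypertensive, beta-blocker, LABA, inhaled corticosteroid). Codes
#' absent from the table are treated as class `other`.
#'
#' @return data.frame with columns `code` and `class`.
#' @export
default_codelists <- function() {
  data.frame(
    code = c("COPD", "IHD", "HF", "STROKE", "CVDEATH",
             "AF", "CKD", "DIABETES", "RA", "SMI",
             "ANTIHTN", "BETABLOCKER", "LABA", "ICS"),
    class = c("copd", "ihd", "hf", "stroke", "cv_death",
              "af", "ckd", "diabetes", "ra", "smi",
              "antihypertensive", "beta_blocker", "laba", "ics"),
    stringsAsFactors = FALSE
  )
}

.read_csv <- function(path) {
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = NULL, fileEncoding = "UTF-8")
}

.require_columns <- function(df, cols, what, path) {
  missing <- setdiff(cols, names(df))
  .assert(length(missing) == 0L,
          "schema error in %s (%s): missing column(s) %s",
          what, path, paste(missing, collapse = ", "))
}

# parse a column with a row-level validator; collects 1-based data row
# numbers (header excluded) of offending rows into `errs`
.check_rows <- function(ok, what, path, field, errs) {
  if (all(ok)) return(errs)
  bad <- which(!ok)
  c(errs, sprintf("%s (%s): invalid %s in row(s) %s", what, path, field,
                  paste(utils::head(bad, 5L), collapse = ", ")))
}

.parse_date <- function(x) as.Date(x, format = "%Y-%m-%d")

#' Read the raw EHR tables
#'
#' Reads and type-checks the three input tables: `patients`
#' (patient_id, sex, year_of_birth, smoking, registration_start,
#' registration_end), `events` (patient_id, date, code, kind, source) and
#' `measurements` (patient_id, date, kind, value). Closed-set fields are
#' validated against their vocabularies, dates must be ISO-8601 within
#' [1900-01-01, 2020-12-31], and duplicate patient ids are an integrity
#' error; offending rows are reported with their (data) row numbers.
#'
#' @param paths named character vector or list with entries `patients`,
#'   `events`, `measurements`, or a directory containing `patients.csv`,
#'   `events.csv` and `measurements.csv`.
#' @return list with typed data.frames `patients`, `events`,
#'   `measurements`.
#' @export
read_tables <- function(paths) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- file.path(paths, c(patients = "patients.csv",
                                events = "events.csv",
                                measurements = "measurements.csv"))
    names(paths) <- c("patients", "events", "measurements")
  }
  .assert(all(c("patients", "events", "measurements") %in% names(paths)),
          "paths must name patients, events and measurements files")
  errs <- character()

  pt <- .read_csv(paths[["patients"]])
  .require_columns(pt, c("patient_id", "sex", "year_of_birth", "smoking",
                         "registration_start", "registration_end"),
                   "patients", paths[["patients"]])
  if (nrow(pt)) {
    .assert(!anyDuplicated(pt$patient_id),
            "integrity error: duplicate patient_id in patients table (%s)",
            paste(pt$patient_id[duplicated(pt$patient_id)][1]))
    smoking <- ifelse(pt$smoking == "", "missing", pt$smoking)
    errs <- .check_rows(pt$sex %in% .SEX_LEVELS, "patients",
                        paths[["patients"]], "sex", errs)
    errs <- .check_rows(smoking %in% .SMOKING_LEVELS, "patients",
                        paths[["patients"]], "smoking", errs)
    yob <- suppressWarnings(as.integer(pt$year_of_birth))
    errs <- .check_rows(!is.na(yob), "patients", paths[["patients"]],
                        "year_of_birth", errs)
    rs <- .parse_date(pt$registration_start)
    re <- .parse_date(pt$registration_end)
    errs <- .check_rows(!is.na(rs), "patients", paths[["patients"]],
                        "registration_start", errs)
    errs <- .check_rows(!is.na(re), "patients", paths[["patients"]],
                        "registration_end", errs)
    errs <- .check_rows(is.na(rs) | is.na(re) | rs <= re, "patients",
                        paths[["patients"]], "registration interval", errs)
    patients <- data.frame(patient_id = pt$patient_id, sex = pt$sex,
                           year_of_birth = yob, smoking = smoking,
                           registration_start = rs, registration_end = re,
                           stringsAsFactors = FALSE)
  } else {
    patients <- data.frame(patient_id = character(), sex = character(),
                           year_of_birth = integer(),
                           smoking = character(),
                           registration_start = as.Date(character()),
                           registration_end = as.Date(character()),
                           stringsAsFactors = FALSE)
  }

  ev <- .read_csv(paths[["events"]])
  .require_columns(ev, c("patient_id", "date", "code", "kind", "source"),
                   "events", paths[["events"]])
  if (nrow(ev)) {
    d <- .parse_date(ev$date)
    errs <- .check_rows(!is.na(d) & d >= .DATE_MIN & d <= .DATE_MAX,
                        "events", paths[["events"]], "date", errs)
    errs <- .check_rows(nzchar(ev$code), "events", paths[["events"]],
                        "code", errs)
    errs <- .check_rows(ev$kind %in% .EVENT_KINDS, "events",
                        paths[["events"]], "kind", errs)
    errs <- .check_rows(ev$source %in% .EVENT_SOURCES, "events",
                        paths[["events"]], "source", errs)
    events <- data.frame(patient_id = ev$patient_id, date = d,
                         code = ev$code, kind = ev$kind,
                         source = ev$source, stringsAsFactors = FALSE)
  } else {
    events <- data.frame(patient_id = character(),
                         date = as.Date(character()), code = character(),
                         kind = character(), source = character(),
                         stringsAsFactors = FALSE)
  }

  ms <- .read_csv(paths[["measurements"]])
  .require_columns(ms, c("patient_id", "date", "kind", "value"),
                   "measurements", paths[["measurements"]])
  if (nrow(ms)) {
    d <- .parse_date(ms$date)
    v <- suppressWarnings(as.numeric(ms$value))
    errs <- .check_rows(!is.na(d), "measurements", paths[["measurements"]],
                        "date", errs)
    errs <- .check_rows(is.finite(v), "measurements",
                        paths[["measurements"]], "value", errs)
    errs <- .check_rows(ms$kind %in% .MEASUREMENT_KINDS, "measurements",
                        paths[["measurements"]], "kind", errs)
    measurements <- data.frame(patient_id = ms$patient_id, date = d,
                               kind = ms$kind, value = v,
                               stringsAsFactors = FALSE)
  } else {
    measurements <- data.frame(patient_id = character(),
                               date = as.Date(character()),
                               kind = character(), value = numeric(),
                               stringsAsFactors = FALSE)
  }

  .assert(length(errs) == 0L, "integrity error:\n%s",
          paste(errs, collapse = "\n"))
  list(patients = patients, events = events, measurements = measurements)
}

#' Write the raw EHR tables
#'
#' Inverse of [read_tables()]: writes `patients.csv`, `events.csv` and
#' `measurements.csv` (comma-separated UTF-8, header row, dates ISO-8601,
#' missing values as empty fields) into a directory. A write followed by a
#' read is the identity on values.
#'
#' @param tables list with `patients`, `events`, `measurements`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_tables <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    for (cl in names(df)) if (inherits(df[[cl]], "Date"))
      df[[cl]] <- format(df[[cl]], "%Y-%m-%d")
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE, na = "", fileEncoding = "UTF-8")
  }
  wr(tables$patients, "patients.csv")
  wr(tables$events, "events.csv")
  wr(tables$measurements, "measurements.csv")
  invisible(dir)
}

#' Read/write a flat key=value configuration file
#'
#' @param path file path.
#' @return named character vector of settings.
#' @keywords internal
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines), invert = TRUE)
  .assert(all(lengths(kv) == 2L), "malformed config line in %s", path)
  stats::setNames(trimws(vapply(kv, `[`, "", 2L)),
                  trimws(vapply(kv, `[`, "", 1L)))
}

#' @rdname read_config_file
#' @param x named vector/list of settings.
#' @export
write_config_file <- function(x, path) {
  writeLines(paste0(names(x), "=", unlist(lapply(x, paste, collapse = ","))),
             path)
  invisible(path)
}
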