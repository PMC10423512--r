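#' @keywords internal
"_PACKAGE"

# Shared category machinery: six SBP exposure categories with half-open
# integer edges. The reference category (120-129 mm Hg) is index 2.

.sbp_levels <- function(edges = c(120, 130, 140, 150, 160)) {
  k <- length(edges) + 1L
  labs <- character(k)
  labs[1] <- paste0("<", edges[1])
  for (i in seq_len(k - 2L)) {
    labs[i + 1L] <- paste0(edges[i], "-", edges[i + 1L] - 1L)
  }
  labs[k] <- paste0(">=", edges[k - 1L])
  labs
}

#' Assign systolic blood pressure categories
#'
#' Maps mean SBP values (mm Hg) onto the six exposure categories
#' `<120, 120-129, 130-139, 140-149, 150-159, >=160` using half-open
#' intervals `[120,130), [130,140), ...`; values of exactly 160 fall in the
#' top category.
#'
#' @param x numeric vector of mean SBP values in mm Hg.
#' @param edges strictly increasing cut points (defaults to the standard
#'   120/130/140/150/160 edges).
#' @return a factor with one level per category, in increasing SBP order.
#' @examples
#' sbp_category(c(119.99, 120, 129.67, 160))
#' @export
sbp_category <- function(x, edges = c(120, 130, 140, 150, 160)) {
  stopifnot(is.numeric(edges), all(diff(edges) > 0))
  idx <- findInterval(x, edges) + 1L
  factor(.sbp_levels(edges)[idx], levels = .sbp_levels(edges))
}

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == round(x) && x > 0

# days-per-year arithmetic is fixed: 12 months = 365 days, 5 years = 1825,
# 6 years = 2190. All windows half-open [start, end).
.DAYS_YEAR <- 365L
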