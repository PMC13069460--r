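#' Exposure schedules for repeated parental depression measurements
#'
#' An exposure schedule is the ordered set of occasions at which a parent's
#' depressive symptoms (EPDS, 0--30) were measured, expressed in years of
#' offspring developmental age. Prenatal occasions are negative: 18 weeks'
#' gestation is -0.42 y and 32 weeks' gestation -0.15 y relative to a term
#' birth at 40 weeks. The default maternal schedule has 12 occasions
#' (twice in pregnancy; 8 weeks; 8, 21, 33 months; 5, 6, 8, 11, 18, 21
#' years); the default paternal schedule has 10 (once in pregnancy and no
#' measurement at 18 years).
#'
#' @param role `"maternal"` or `"paternal"`.
#' @return A tibble of class `exposure_schedule` with columns `label` and
#'   `age` (years, strictly increasing) and a `role` attribute.
#' @examples
#' default_schedule("maternal")
#' truncate_schedule(default_schedule("maternal"), 11)
#' @export
default_schedule <- function(role = c("maternal", "paternal")) {
  role <- match.arg(role)
  if (role == "maternal") {
    labels <- c("18wk_gest", "32wk_gest", "8wk", "8mo", "21mo", "33mo",
                "5yr", "6yr", "8yr", "11yr", "18yr", "21yr")
    ages <- c(-0.42, -0.15, 0.154, 0.667, 1.75, 2.75, 5, 6, 8, 11, 18, 21)
  } else {
    labels <- c("18wk_gest", "8wk", "8mo", "21mo", "33mo",
                "5yr", "6yr", "8yr", "11yr", "21yr")
    ages <- c(-0.42, 0.154, 0.667, 1.75, 2.75, 5, 6, 8, 11, 21)
  }
  exposure_schedule(ages, labels, role)
}

#' Construct an exposure schedule
#'
#' @param ages Strictly increasing numeric vector of measurement ages in
#'   years relative to birth (prenatal ages negative); at least 3 points.
#' @param labels Optional character labels, one per age.
#' @param role `"maternal"` or `"paternal"`.
#' @return A tibble of class `exposure_schedule`.
#' @export
exposure_schedule <- function(ages, labels = NULL, role = c("maternal", "paternal")) {
  role <- match.arg(role)
  ages <- as.numeric(ages)
  if (length(ages) < 3L) {
    stop("an exposure schedule needs at least 3 occasions", call. = FALSE)
  }
  if (any(!is.finite(ages)) || any(diff(ages) <= 0)) {
    stop("schedule ages must be finite and strictly increasing", call. = FALSE)
  }
  if (is.null(labels)) labels <- sprintf("t%02d", seq_along(ages))
  stopifnot(length(labels) == length(ages))
  out <- tibble::tibble(label = as.character(labels), age = ages)
  class(out) <- c("exposure_schedule", class(out))
  attr(out, "role") <- role
  out
}

#' Truncate a schedule at a maximum developmental age
#'
#' Outcome-specific truncation: e.g. psychotic experiences are assessed
#' "since age 12", so exposure is considered from pregnancy through age 11
#' only.
#'
#' @param schedule An [exposure_schedule()].
#' @param max_age Keep occasions with `age <= max_age`.
#' @return The truncated `exposure_schedule` (order preserved).
#' @export
truncate_schedule <- function(schedule, max_age) {
  stopifnot(inherits(schedule, "exposure_schedule"), is.numeric(max_age))
  keep <- schedule$age <= max_age
  if (sum(keep) < 3L) {
    stop("truncation would leave fewer than 3 occasions", call. = FALSE)
  }
  out <- schedule[keep, ]
  class(out) <- class(schedule)
  attr(out, "role") <- attr(schedule, "role")
  out
}

#' @export
print.exposure_schedule <- function(x, ...) {
  cat(sprintf("<exposure_schedule: %s, %d occasions, %.2f to %.2f y>\n",
              attr(x, "role"), nrow(x), min(x$age), max(x$age)))
  NextMethod()
}

schedule_role <- function(schedule) attr(schedule, "role")

#' Exposure column names for a schedule
#'
#' Cohort tables store one column per measurement occasion, named
#' `<prefix>_epds_<label>` with prefix `mat` or `pat`.
#'
#' @param schedule An [exposure_schedule()].
#' @return Character vector of column names.
#' @export
schedule_columns <- function(schedule) {
  prefix <- if (identical(attr(schedule, "role"), "paternal")) "pat" else "mat"
  paste0(prefix, "_epds_", schedule$label)
}
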