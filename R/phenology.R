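#' Estimate the dormancy release date from a forcing-test bud-break series
#'
#' Branches sampled fortnightly are held 10 days under forcing conditions
#' and the percentage of flower buds reaching BBCH stage 53 is recorded.
#' The dormancy release date is the earliest observation date at which this
#' percentage reaches `threshold` (50% by default); with
#' `interpolate = TRUE` the linearly interpolated crossing date between the
#' bracketing observations is returned instead.
#'
#' @param dates observation dates (coerced with `as.Date`), strictly
#'   increasing.
#' @param percent percentage of buds at BBCH 53, in \[0, 100\].
#' @param threshold release threshold (default 50).
#' @param interpolate linearly interpolate the crossing date (default
#'   FALSE).
#' @param strict require strictly greater than `threshold` instead of >=
#'   (default FALSE).
#' @return list of class `release_estimate`: `released` (logical), `date`
#'   (`Date`, `NA` when the threshold is never reached), `threshold`.
#' @export
estimate_dormancy_release <- function(dates, percent, threshold = 50,
                                      interpolate = FALSE, strict = FALSE) {
  dates <- as.Date(dates)
  if (length(dates) < 2) stop("need at least 2 observations")
  if (length(dates) != length(percent)) stop("dates/percent length mismatch")
  if (any(diff(as.numeric(dates)) <= 0)) stop("dates must be strictly increasing")
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100))
    stop("percentages must lie in [0, 100]")
  reached <- if (strict) percent > threshold else percent >= threshold
  if (!any(reached)) {
    out <- list(released = FALSE, date = as.Date(NA), threshold = threshold)
    class(out) <- "release_estimate"
    return(out)
  }
  i <- which(reached)[1]
  date <- if (!interpolate || i == 1) {
    dates[i]
  } else {
    # linear crossing between the last sub-threshold and first
    # at-or-above-threshold observations
    p0 <- percent[i - 1]; p1 <- percent[i]
    frac <- (threshold - p0) / (p1 - p0)
    dates[i - 1] + frac * as.numeric(dates[i] - dates[i - 1])
  }
  out <- list(released = TRUE, date = date, threshold = threshold)
  class(out) <- "release_estimate"
  out
}

#' @export
print.release_estimate <- function(x, ...) {
  if (x$released)
    cat("Dormancy released on", format(x$date), "(threshold", x$threshold, "%)\n")
  else
    cat("Dormancy not released (threshold", x$threshold, "% never reached)\n")
  invisible(x)
}

#' Construct a per-cultivar stage calendar
#'
#' The windows are ordered and non-overlapping: organogenesis, then
#' paradormancy until endodormancy onset, endodormancy until the release
#' window, a release window of `release_window_days` centred on the
#' estimated release date, and ecodormancy until flowering. The
#' organogenesis (July-August), paradormancy (September) and endodormancy
#' onset (1 October) defaults reflect the conventional, somewhat arbitrary
#' delimitation of the pre-dormancy phases.
#'
#' @param cultivar cultivar name.
#' @param release_date estimated dormancy release date.
#' @param flowering_date flowering date (end of ecodormancy).
#' @param organogenesis_start,organogenesis_end organogenesis window.
#' @param endodormancy_onset start of endodormancy (paradormancy runs from
#'   the end of organogenesis to the day before).
#' @param release_window_days width of the dormancy-release window
#'   (default 14, i.e. +/- 7 days).
#' @return list of class `stage_calendar`.
#' @export
stage_calendar <- function(cultivar, release_date, flowering_date,
                           organogenesis_start = "2015-07-01",
                           organogenesis_end = "2015-08-31",
                           endodormancy_onset = "2015-10-01",
                           release_window_days = 14) {
  cal <- list(cultivar = cultivar,
              organogenesis_start = as.Date(organogenesis_start),
              organogenesis_end = as.Date(organogenesis_end),
              endodormancy_onset = as.Date(endodormancy_onset),
              release_date = as.Date(release_date),
              flowering_date = as.Date(flowering_date),
              release_window_days = release_window_days)
  with(cal, {
    if (!(organogenesis_start <= organogenesis_end &&
          organogenesis_end < endodormancy_onset &&
          endodormancy_onset < release_date &&
          release_date < flowering_date))
      stop("calendar windows must be ordered: organogenesis < paradormancy < ",
           "endodormancy onset < release < flowering")
  })
  class(cal) <- "stage_calendar"
  cal
}

#' Assign the five stage labels to samples from a stage calendar
#'
#' Dates in the organogenesis window map to organogenesis; from its end to
#' endodormancy onset, paradormancy; from onset to the start of the release
#' window, endodormancy; within +/- `release_window_days`/2 of the release
#' date, dormancy release; and from there to flowering, ecodormancy. A
#' sample date outside all windows is an error.
#'
#' @param dates sample dates (coerced with `as.Date`).
#' @param calendar a [stage_calendar()].
#' @return character vector of stage labels.
#' @export
assign_stage_labels <- function(dates, calendar) {
  if (!inherits(calendar, "stage_calendar")) stop("calendar must be a stage_calendar")
  dates <- as.Date(dates)
  half <- calendar$release_window_days / 2
  rel_lo <- calendar$release_date - half
  rel_hi <- calendar$release_date + half
  out <- character(length(dates))
  for (i in seq_along(dates)) {
    d <- dates[i]
    out[i] <- if (d >= calendar$organogenesis_start && d <= calendar$organogenesis_end)
      "organogenesis"
    else if (d > calendar$organogenesis_end && d < calendar$endodormancy_onset)
      "paradormancy"
    else if (d >= calendar$endodormancy_onset && d < rel_lo)
      "endodormancy"
    else if (d >= rel_lo && d <= rel_hi)
      "dormancy_release"
    else if (d > rel_hi && d <= calendar$flowering_date)
      "ecodormancy"
    else
      stop("sample date ", format(d), " outside the ", calendar$cultivar,
           " calendar (", format(calendar$organogenesis_start), " to ",
           format(calendar$flowering_date), ")")
  }
  out
}
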