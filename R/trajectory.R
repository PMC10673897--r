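#' Daily percent weight-change series
#'
#' A vector of percent weight change relative to baseline, on an integer
#' daily grid starting at day 0 (the first weight entry). Values are kept on
#' the percent scale throughout (-5 means a 5% loss).
#'
#' @param values Numeric vector, `values[1]` is day 0 and must be 0.
#' @param last_observed_day Last day backed by an actual entry; days beyond
#'   it (if present) are extrapolated.
#' @param baseline_weight Baseline weight in kg.
#' @return An object of class `daily_series`.
#' @export
daily_series <- function(values, last_observed_day, baseline_weight) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("series values must be nonempty and finite", call. = FALSE)
  if (abs(values[1]) > 1e-9)
    stop("a percent-change series must start at 0 on day 0", call. = FALSE)
  last_observed_day <- as.integer(last_observed_day)
  stopifnot(last_observed_day >= 0L, baseline_weight > 0)
  structure(list(values = values, last_observed_day = last_observed_day,
                 baseline_weight = baseline_weight),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat(sprintf(
    "<daily_series> days 0-%d (observed to %d), baseline %.1f kg, final %+.2f%%\n",
    length(x$values) - 1L, x$last_observed_day, x$baseline_weight,
    x$values[length(x$values)]))
  invisible(x)
}

#' Value of a daily series at a given day
#' @param series A [daily_series].
#' @param day Integer day (0-based).
#' @return Percent weight change at that day.
#' @export
series_value <- function(series, day) {
  stopifnot(day >= 0L, day <= length(series$values) - 1L)
  series$values[day + 1L]
}

#' Percent weight-change series from a weight log
#'
#' Converts raw weights to percent change relative to the baseline (day 0)
#' entry and linearly interpolates the days between entries. The series ends
#' at the last entry day.
#'
#' @param rec A [participant_record] with at least two entries, the first at
#'   day 0.
#' @return A [daily_series].
#' @export
percent_change_series <- function(rec) {
  e <- rec$entries
  if (nrow(e) < 2L)
    stop("insufficient data: at least two weight entries are required",
         call. = FALSE)
  if (e$day[1] != 0L)
    stop("first entry must be at day 0", call. = FALSE)
  w0 <- e$weight[1]
  pct <- 100 * (e$weight - w0) / w0
  grid <- 0:max(e$day)
  vals <- stats::approx(e$day, pct, xout = grid, method = "linear")$y
  daily_series(vals, last_observed_day = max(e$day), baseline_weight = w0)
}

#' Extrapolate (or truncate) a series to a target end day
#'
#' Beyond the last observed day, the percent change continues at the average
#' rate between baseline and the last observed entry:
#' `value(d) = d * value(last)/last`. If the series already reaches
#' `end_day`, it is truncated there with no extrapolation.
#'
#' @param series A [daily_series].
#' @param end_day Target end day (>= 1).
#' @return A [daily_series] of length `end_day + 1`.
#' @export
extrapolate_to <- function(series, end_day) {
  end_day <- as.integer(end_day)
  stopifnot(end_day >= 0L)
  lod <- series$last_observed_day
  if (lod >= end_day) {
    return(daily_series(series$values[1:(end_day + 1L)],
                        last_observed_day = min(lod, end_day),
                        baseline_weight = series$baseline_weight))
  }
  if (lod == 0L)
    stop("cannot extrapolate from a single day-0 observation (undefined slope)",
         call. = FALSE)
  slope <- series$values[lod + 1L] / lod
  ext <- ((lod + 1L):end_day) * slope
  daily_series(c(series$values[1:(lod + 1L)], ext),
               last_observed_day = lod,
               baseline_weight = series$baseline_weight)
}

#' Prediction time frames
#'
#' The nine prediction time frames span 0.5, 1, 2, ..., 8 months from
#' baseline, with one month defined as 30 days.
#'
#' @param months Frame length in months (one of 0.5, 1, 2, ..., 8).
#' @return `time_frame()` returns a single frame (list with `label`,
#'   `months`, `end_day`); `time_frames()` the list of all nine.
#' @export
time_frame <- function(months) {
  grid <- c(0.5, 1, 2, 3, 4, 5, 6, 7, 8)
  if (!months %in% grid)
    stop("months must be one of 0.5, 1, 2, ..., 8", call. = FALSE)
  structure(list(label = format(months), months = months,
                 end_day = as.integer(months * 30)),
            class = "time_frame")
}

#' @rdname time_frame
#' @export
time_frames <- function() lapply(c(0.5, 1, 2, 3, 4, 5, 6, 7, 8), time_frame)

frame_grid_ends <- function() as.integer(c(0.5, 1, 2, 3, 4, 5, 6, 7, 8) * 30)

#' Restrict a series to a prediction time frame
#'
#' Limits the series to days 0..frame end, extrapolating via
#' [extrapolate_to()] when observations end earlier.
#'
#' @param series A [daily_series].
#' @param frame A [time_frame()].
#' @return A [daily_series] with `frame$end_day + 1` values.
#' @export
restrict_to_frame <- function(series, frame) {
  stopifnot(inherits(frame, "time_frame"))
  extrapolate_to(series, frame$end_day)
}

#' Body mass index
#'
#' @param weight_kg Weight in kg (positive).
#' @param height_cm Height in cm (positive).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0) || any(height_cm <= 0))
    stop("weight and height must be positive", call. = FALSE)
  weight_kg / (height_cm / 100)^2
}

# Series over the frame using only in-frame entries, as done when a model is
# applied to a partially observed individual: interpolate to the last entry
# within the frame, then extrapolate to the frame end.
frame_series <- function(rec, frame) {
  e <- rec$entries[rec$entries$day <= frame$end_day, , drop = FALSE]
  if (nrow(e) < 2L)
    stop("insufficient data: fewer than two entries within the time frame",
         call. = FALSE)
  sub <- participant_record(rec$id, rec$height_cm, e, rec$medication_flag)
  extrapolate_to(percent_change_series(sub), frame$end_day)
}
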