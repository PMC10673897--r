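#' Participant weight-log record
#'
#' A participant record couples an identifier and baseline height with an
#' ordered log of self-reported weights. Days are integer offsets from the
#' participant's first entry (day 0 = first entry).
#'
#' @param id Participant identifier (coerced to character).
#' @param height_cm Baseline height in centimetres (positive).
#' @param entries Data frame with integer column `day` (>= 0, strictly
#'   increasing) and positive numeric column `weight` (kg).
#' @param medication_flag `TRUE` if the participant has a known prescription
#'   of weight-loss medication.
#' @return An object of class `participant_record`.
#' @export
participant_record <- function(id, height_cm, entries, medication_flag = FALSE) {
  id <- as.character(id)
  stopifnot(length(id) == 1L, nzchar(id))
  if (!is.numeric(height_cm) || length(height_cm) != 1L || height_cm <= 0)
    stop("height_cm must be a single positive number", call. = FALSE)
  if (!is.data.frame(entries) || !all(c("day", "weight") %in% names(entries)))
    stop("entries must be a data frame with columns 'day' and 'weight'",
         call. = FALSE)
  entries <- data.frame(day = as.integer(entries$day),
                        weight = as.numeric(entries$weight))
  entries <- entries[order(entries$day), , drop = FALSE]
  rownames(entries) <- NULL
  if (nrow(entries) == 0L) stop("entries must be nonempty", call. = FALSE)
  if (any(entries$day < 0L)) stop("entry days must be >= 0", call. = FALSE)
  if (anyDuplicated(entries$day))
    stop("entry days must be strictly increasing", call. = FALSE)
  if (any(!is.finite(entries$weight)) || any(entries$weight <= 0))
    stop("weights must be positive and finite", call. = FALSE)
  structure(list(id = id, height_cm = height_cm, entries = entries,
                 medication_flag = isTRUE(medication_flag)),
            class = "participant_record")
}

#' @export
print.participant_record <- function(x, ...) {
  cat(sprintf("<participant %s> %d entries, days %d-%d, height %.1f cm%s\n",
              x$id, nrow(x$entries), min(x$entries$day), max(x$entries$day),
              x$height_cm,
              if (x$medication_flag) ", weight-loss medication" else ""))
  invisible(x)
}

#' Read a cohort of weight logs
#'
#' Reads a weight-log CSV (columns `id`, `day` or ISO-8601 `date`, and
#' `weight_kg`) and a height table (columns `id`, `height_cm`, optional
#' `medication` flag). Dates are converted to day offsets from each
#' participant's first entry; duplicate (id, day) rows are collapsed to their
#' mean weight; entries are sorted by day and records by id.
#'
#' @param path Path to the weight-log CSV.
#' @param height_table Path to the height CSV.
#' @return List of [participant_record] objects, sorted by id.
#' @export
read_cohort <- function(path, height_table) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df))
    stop("weight log is missing required column 'id'", call. = FALSE)
  if (!"weight_kg" %in% names(df))
    stop("weight log is missing required column 'weight_kg'", call. = FALSE)
  if (!any(c("day", "date") %in% names(df)))
    stop("weight log must have a 'day' or 'date' column", call. = FALSE)

  wt <- suppressWarnings(as.numeric(df$weight_kg))
  bad <- which(is.na(wt) & !is.na(df$weight_kg) & df$weight_kg != "")
  if (length(bad))
    stop(sprintf("non-numeric weight_kg in row %d ('%s')",
                 bad[1], df$weight_kg[bad[1]]), call. = FALSE)
  df$weight_kg <- wt

  if ("day" %in% names(df)) {
    day <- suppressWarnings(as.integer(df$day))
    if (anyNA(day)) stop("non-integer 'day' values in weight log", call. = FALSE)
    df$.day <- day
  } else {
    d <- as.Date(df$date, format = "%Y-%m-%d")
    if (anyNA(d)) stop("unparseable ISO-8601 'date' values in weight log",
                       call. = FALSE)
    df$.day <- as.integer(d - as.Date("1970-01-01"))
  }

  ht <- utils::read.csv(height_table, stringsAsFactors = FALSE)
  if (!all(c("id", "height_cm") %in% names(ht)))
    stop("height table must have columns 'id' and 'height_cm'", call. = FALSE)
  ht$id <- as.character(ht$id)
  med <- if ("medication" %in% names(ht))
    setNames(as.logical(ht$medication), ht$id) else NULL
  hmap <- setNames(as.numeric(ht$height_cm), ht$id)

  ids <- sort(unique(as.character(df$id)))
  cohort <- lapply(ids, function(i) {
    sub <- df[as.character(df$id) == i, , drop = FALSE]
    # collapse duplicate days to the mean weight, then anchor day 0
    agg <- stats::aggregate(weight_kg ~ .day, data = sub, FUN = mean)
    agg <- agg[order(agg$.day), , drop = FALSE]
    if (!i %in% names(hmap))
      stop(sprintf("no height for participant '%s'", i), call. = FALSE)
    participant_record(
      id = i, height_cm = hmap[[i]],
      entries = data.frame(day = agg$.day - min(agg$.day),
                           weight = agg$weight_kg),
      medication_flag = if (!is.null(med)) isTRUE(med[[i]]) else FALSE)
  })
  cohort
}

#' Write a cohort in the weight-log CSV dialect
#'
#' Inverse of [read_cohort()]: writes the weight log and, optionally, the
#' height table read back by `read_cohort`.
#'
#' @param cohort List of [participant_record] objects.
#' @param path Output path for the weight-log CSV.
#' @param height_path Optional output path for the height table.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path, height_path = NULL) {
  rows <- do.call(rbind, lapply(cohort, function(r)
    data.frame(id = r$id, day = r$entries$day, weight_kg = r$entries$weight)))
  utils::write.csv(rows, path, row.names = FALSE)
  if (!is.null(height_path)) {
    ht <- do.call(rbind, lapply(cohort, function(r)
      data.frame(id = r$id, height_cm = r$height_cm,
                 medication = r$medication_flag)))
    utils::write.csv(ht, height_path, row.names = FALSE)
  }
  invisible(path)
}

#' Participant exclusion configuration
#'
#' Screening thresholds applied before model training or validation. Setting
#' a threshold to `NULL` (or `exclude_medication = FALSE`) disables that
#' criterion.
#'
#' @param max_daily_change_kg Exclude if any pair of consecutive entries
#'   implies more than this absolute weight change per day (kg/day).
#' @param min_entries Exclude if fewer than this many entries fall within the
#'   follow-up window (the first `min_span_days` days, or all entries when the
#'   span criterion is disabled).
#' @param min_span_days Exclude if (last day - first day) is below this span.
#' @param min_height_cm Exclude if height is at or below this bound
#'   (the bound itself is excluded: a height of exactly `min_height_cm` fails).
#' @param exclude_medication Exclude participants flagged as using
#'   weight-loss medication.
#' @param require_entry_within_days If non-`NULL`, require at least one entry
#'   within the first so-many days (validation-style criterion).
#' @return An object of class `exclusion_config`.
#' @export
exclusion_config <- function(max_daily_change_kg = 1.5, min_entries = 2L,
                             min_span_days = 270L, min_height_cm = 100,
                             exclude_medication = TRUE,
                             require_entry_within_days = NULL) {
  for (v in list(max_daily_change_kg, min_entries, min_span_days,
                 min_height_cm, require_entry_within_days))
    if (!is.null(v) && (!is.numeric(v) || v <= 0))
      stop("exclusion thresholds must be positive", call. = FALSE)
  structure(list(max_daily_change_kg = max_daily_change_kg,
                 min_entries = min_entries, min_span_days = min_span_days,
                 min_height_cm = min_height_cm,
                 exclude_medication = isTRUE(exclude_medication),
                 require_entry_within_days = require_entry_within_days),
            class = "exclusion_config")
}

#' Validation-style exclusion configuration
#'
#' Screening used for an external validation cohort: the medication criterion
#' is dropped (medication status is typically unrecorded there) and the
#' follow-up-span requirement is waived so that individuals truncated before
#' the 9-month mark can still be validated via extrapolation; at least one
#' entry within the first 270 days is required instead.
#'
#' @param ... Overrides passed to [exclusion_config()].
#' @return An `exclusion_config`.
#' @export
validation_exclusion_config <- function(...) {
  defaults <- list(exclude_medication = FALSE, min_span_days = NULL,
                   require_entry_within_days = 270L)
  args <- utils::modifyList(defaults, list(...))
  do.call(exclusion_config, args)
}

exclusion_reasons <- function(rec, cfg) {
  reasons <- character(0)
  d <- rec$entries$day
  w <- rec$entries$weight
  if (cfg$exclude_medication && rec$medication_flag)
    reasons <- c(reasons, "medication")
  if (!is.null(cfg$min_entries)) {
    window <- cfg$min_span_days %||% Inf
    if (sum(d <= window) < cfg$min_entries)
      reasons <- c(reasons, "min_entries")
  }
  if (!is.null(cfg$max_daily_change_kg) && length(d) >= 2L) {
    rate <- abs(diff(w)) / diff(d)
    if (any(rate > cfg$max_daily_change_kg))
      reasons <- c(reasons, "max_daily_change")
  }
  if (!is.null(cfg$min_span_days) && (max(d) - min(d)) < cfg$min_span_days)
    reasons <- c(reasons, "min_span")
  if (!is.null(cfg$min_height_cm) && rec$height_cm <= cfg$min_height_cm)
    reasons <- c(reasons, "min_height")
  if (!is.null(cfg$require_entry_within_days) &&
      !any(d <= cfg$require_entry_within_days))
    reasons <- c(reasons, "no_entry_within_window")
  reasons
}

#' Apply participant exclusion criteria
#'
#' A record is kept iff it violates no enabled criterion. The daily-change
#' criterion is evaluated between consecutive raw entries as
#' |change in weight| / gap in days.
#'
#' @param cohort List of [participant_record] objects (nonempty).
#' @param cfg An [exclusion_config()].
#' @return List with `kept` (records passing all criteria) and `log`, a data
#'   frame with one row per excluded id and a comma-joined `criteria` column.
#' @export
apply_exclusions <- function(cohort, cfg = exclusion_config()) {
  stopifnot(length(cohort) > 0L)
  reasons <- lapply(cohort, exclusion_reasons, cfg = cfg)
  drop <- vapply(reasons, function(r) length(r) > 0L, logical(1))
  log <- if (any(drop)) {
    data.frame(id = vapply(cohort[drop], `[[`, character(1), "id"),
               criteria = vapply(reasons[drop], paste, character(1),
                                 collapse = ","),
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = character(0), criteria = character(0),
               stringsAsFactors = FALSE)
  }
  list(kept = cohort[!drop], log = log)
}
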