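#' Trajectory archetypes for the five weight-change classes
#'
#' Each archetype is an exponential-plateau mean curve
#' `a * (1 - exp(-d / tau))` over days 0-270: an initial change that levels
#' off, the shape the outcome clusters exhibit in practice. Default terminal
#' values at day 270 sit inside the class bands: high loss about -12%
#' (beyond the 10% loss mark), moderate loss about -7% (the 5-10% band),
#' insufficient loss -1.5%, low gain +1.5%, high gain +5%.
#'
#' @param terminal Named numeric vector of day-270 percent changes, one per
#'   five-class label, ordered strictly increasing across
#'   `high_loss < moderate_loss < insufficient_loss < low_gain < high_gain`.
#' @param tau Named numeric vector of plateau time constants (days).
#' @return List of archetype specs (`name`, `terminal`, `tau`, and `curve`,
#'   a function of day).
#' @export
archetype_specs <- function(terminal = c(high_loss = -12, moderate_loss = -7,
                                         insufficient_loss = -1.5,
                                         low_gain = 1.5, high_gain = 5),
                            tau = c(high_loss = 75, moderate_loss = 75,
                                    insufficient_loss = 60, low_gain = 150,
                                    high_gain = 150)) {
  stopifnot(identical(names(terminal), FIVE_CLASSES),
            all(diff(terminal) > 0), all(tau > 0))
  lapply(FIVE_CLASSES, function(cl) {
    a <- terminal[[cl]] / (1 - exp(-270 / tau[[cl]]))
    tcl <- tau[[cl]]
    list(name = cl, terminal = terminal[[cl]], tau = tcl,
         curve = local({
           a_ <- a; t_ <- tcl
           function(d) a_ * (1 - exp(-d / t_))
         }))
  })
}

#' Simulation configuration for synthetic cohorts
#'
#' Defaults emulate the cohort statistics of the original study conditions:
#' a training-style cohort of about 300 participants (5 x 60) logging
#' 36 +/- 19 entries (range 3-149) over 270 days with 0.5% per-observation
#' measurement noise, or, with `sparse_mode = TRUE`, a validation-style
#' cohort logging 16 +/- 16 entries (range 3-162) with half the individuals
#' truncated before day 270.
#'
#' @param n_per_class Individuals per archetype (length 5).
#' @param noise_sd Per-observation measurement noise, percent of baseline
#'   weight.
#' @param entry_count_mean,entry_count_sd,entry_count_range Entry-count
#'   distribution (normal draw rounded and clipped to the range); defaults
#'   switch with `sparse_mode`.
#' @param span_days Follow-up span.
#' @param sparse_mode Validation-style cohort: sparser logging and a
#'   `truncate_fraction` of individuals followed only to a random day before
#'   `span_days`.
#' @param truncate_fraction Fraction truncated under `sparse_mode`.
#' @param baseline_weight_range,height_range Uniform ranges (kg, cm).
#' @param stress If `TRUE`, disables the guard that keeps simulated
#'   consecutive entries below 1.5 kg/day (used to exercise the exclusion
#'   screen).
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_per_class = rep(60L, 5), noise_sd = 0.5,
                       entry_count_mean = NULL, entry_count_sd = NULL,
                       entry_count_range = NULL, span_days = 270L,
                       sparse_mode = FALSE, truncate_fraction = 0.5,
                       baseline_weight_range = c(75, 135),
                       height_range = c(155, 190), stress = FALSE,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  entry_count_mean <- entry_count_mean %||% (if (sparse_mode) 16 else 36)
  entry_count_sd <- entry_count_sd %||% (if (sparse_mode) 16 else 19)
  entry_count_range <- entry_count_range %||%
    (if (sparse_mode) c(3L, 162L) else c(3L, 149L))
  stopifnot(length(n_per_class) == 5L, all(n_per_class >= 0L),
            noise_sd >= 0, span_days >= 30L,
            entry_count_range[1] >= 2L,
            entry_count_range[2] >= entry_count_range[1],
            truncate_fraction >= 0, truncate_fraction <= 1,
            diff(baseline_weight_range) >= 0, diff(height_range) >= 0)
  structure(list(n_per_class = as.integer(n_per_class), noise_sd = noise_sd,
                 entry_count_mean = entry_count_mean,
                 entry_count_sd = entry_count_sd,
                 entry_count_range = as.integer(entry_count_range),
                 span_days = as.integer(span_days),
                 sparse_mode = isTRUE(sparse_mode),
                 truncate_fraction = truncate_fraction,
                 baseline_weight_range = baseline_weight_range,
                 height_range = height_range, stress = isTRUE(stress),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic cohort with known class labels
#'
#' Each individual draws an archetype, a baseline weight and height, a set
#' of irregular entry days (always including day 0), and observed weights
#' `baseline * (1 + (curve(d) + e_d)/100)` with i.i.d. Gaussian measurement
#' noise `e_d`. Unless `stress` is set, noise draws that would imply more
#' than 1.5 kg/day between consecutive entries are redrawn (and zeroed as a
#' last resort), so default cohorts pass the exclusion screen. Under
#' `sparse_mode`, a fraction of individuals is truncated at a random day
#' before the full span.
#'
#' @param cfg A [sim_config()].
#' @param archetypes Output of [archetype_specs()].
#' @return List with `cohort` (list of [participant_record]) and `truth`
#'   (named character vector: id -> five-class label).
#' @export
generate_cohort <- function(cfg, archetypes = archetype_specs()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    recs <- list()
    truth <- character(0)
    idx <- 0L
    for (a in seq_along(archetypes)) {
      spec <- archetypes[[a]]
      for (j in seq_len(cfg$n_per_class[a])) {
        idx <- idx + 1L
        id <- sprintf("sim_%03d", idx)
        w0 <- runif(1, cfg$baseline_weight_range[1], cfg$baseline_weight_range[2])
        ht <- runif(1, cfg$height_range[1], cfg$height_range[2])
        follow_to <- cfg$span_days
        if (cfg$sparse_mode && runif(1) < cfg$truncate_fraction)
          follow_to <- sample(30:(cfg$span_days - 1L), 1L)
        n_entries <- round(rnorm(1, cfg$entry_count_mean, cfg$entry_count_sd))
        n_entries <- max(cfg$entry_count_range[1],
                         min(cfg$entry_count_range[2], n_entries))
        n_extra <- max(0L, min(n_entries - 2L, follow_to - 1L))
        days <- c(0L, sort(sample(seq_len(follow_to - 1L), n_extra)),
                  follow_to)
        days <- unique(days)
        weights <- numeric(length(days))
        for (k in seq_along(days)) {
          d <- days[k]
          mu <- spec$curve(d)
          eps <- if (d == 0L) 0 else rnorm(1, 0, cfg$noise_sd)
          w <- w0 * (1 + (mu + eps) / 100)
          if (!cfg$stress && k > 1L) {
            gap <- d - days[k - 1L]
            tries <- 0L
            while (abs(w - weights[k - 1L]) / gap > 1.45 && tries < 20L) {
              eps <- rnorm(1, 0, cfg$noise_sd)
              w <- w0 * (1 + (mu + eps) / 100)
              tries <- tries + 1L
            }
            if (abs(w - weights[k - 1L]) / gap > 1.45)
              w <- w0 * (1 + mu / 100)
          }
          weights[k] <- w
        }
        recs[[idx]] <- participant_record(
          id, ht, data.frame(day = days, weight = weights))
        truth[id] <- spec$name
      }
    }
    list(cohort = recs, truth = truth)
  })
}

#' Empirical class prevalence
#'
#' @param truth Nonempty class label vector.
#' @param classes Optional class order; defaults to sorted unique labels.
#' @return Named probability vector summing to 1.
#' @export
class_prevalence <- function(truth, classes = NULL) {
  stopifnot(length(truth) > 0L)
  truth <- as.character(truth)
  classes <- classes %||% sort(unique(truth))
  tab <- table(factor(truth, levels = classes))
  setNames(as.numeric(tab) / length(truth), classes)
}
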