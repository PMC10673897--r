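# Independent oracles and small fixture builders shared across tests.

# Exhaustive enumeration of all monotone warping paths from (1,1) to (n,m);
# intended for series of length <= 6. Independent of the package's DP.
dtw_oracle <- function(a, b, local = "squared", final_sqrt = TRUE) {
  costf <- if (local == "squared") function(x, y) (x - y)^2
           else function(x, y) abs(x - y)
  n <- length(a); m <- length(b)
  best <- Inf
  walk <- function(i, j, acc) {
    acc <- acc + costf(a[i], b[j])
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    if (i < n) walk(i + 1, j, acc)
    if (j < m) walk(i, j + 1, acc)
    if (i < n && j < m) walk(i + 1, j + 1, acc)
    invisible(NULL)
  }
  walk(1, 1, 0)
  if (local == "squared" && final_sqrt) sqrt(best) else best
}

# Brute-force cutoff search written as naive loops: for every adjacent class
# pair, try every observed value of that pair's members as the boundary,
# classify each member explicitly by "x <= v -> lower class", count errors,
# and keep the largest error-minimizing value.
cutoffs_oracle <- function(x, labels, classes) {
  out <- numeric(length(classes) - 1L)
  for (i in seq_len(length(classes) - 1L)) {
    lower <- classes[i]; upper <- classes[i + 1L]
    keep <- labels == lower | labels == upper
    xs <- x[keep]; ls <- labels[keep]
    best_err <- Inf; best_v <- -Inf
    for (v in xs) {
      err <- 0L
      for (j in seq_along(xs)) {
        pred <- if (xs[j] <= v) lower else upper
        if (pred != ls[j]) err <- err + 1L
      }
      if (err < best_err || (err == best_err && v > best_v)) {
        best_err <- err; best_v <- v
      }
    }
    out[i] <- best_v
  }
  out
}

make_record <- function(days, weights, id = "p1", height = 170,
                        medication = FALSE) {
  participant_record(id, height, data.frame(day = days, weight = weights),
                     medication_flag = medication)
}

# Cohort with perfectly linear percent-change trajectories, one slope band
# per five-class label; separable by construction.
linear_cohort <- function(n_per_class = 6L, seed = 1) {
  slopes <- c(high_loss = -12, moderate_loss = -7, insufficient_loss = -1.5,
              low_gain = 1.5, high_gain = 5) / 270
  recs <- list(); truth <- character(0); idx <- 0L
  withr::with_seed(seed, {
    for (cl in names(slopes)) {
      for (j in seq_len(n_per_class)) {
        idx <- idx + 1L
        id <- sprintf("lin_%03d", idx)
        w0 <- runif(1, 80, 120)
        jitter <- runif(1, -0.1, 0.1) / 270   # within-band slope variation
        days <- c(0L, sort(sample(1:239, 18)), 240L, 270L)
        pct <- (slopes[[cl]] + jitter) * days
        recs[[idx]] <- make_record(days, w0 * (1 + pct / 100), id = id)
        truth[id] <- cl
      }
    }
  })
  list(cohort = recs, truth = truth)
}
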