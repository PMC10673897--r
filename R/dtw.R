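#' Dynamic time warping configuration
#'
#' @param local_cost Per-step local cost: `"squared"` (default) or
#'   `"absolute"` difference.
#' @param window Optional Sakoe-Chiba band half-width in days (`NULL` =
#'   unconstrained, the default). Must be at least 1 and at least the length
#'   difference of any pair compared.
#' @param final_sqrt Take the square root of the accumulated cost; applied
#'   only with the squared local cost (the usual convention of DTW
#'   libraries, giving distances on the scale of the data).
#' @return An object of class `dtw_config`.
#' @export
dtw_config <- function(local_cost = c("squared", "absolute"), window = NULL,
                       final_sqrt = TRUE) {
  local_cost <- match.arg(local_cost)
  if (!is.null(window)) {
    window <- as.integer(window)
    if (window < 1L) stop("window must be >= 1", call. = FALSE)
  }
  structure(list(local_cost = local_cost, window = window,
                 final_sqrt = isTRUE(final_sqrt)),
            class = "dtw_config")
}

cfg_cost_type <- function(cfg) if (cfg$local_cost == "squared") 0L else 1L

check_series_arg <- function(x, what) {
  if (!is.numeric(x) || length(x) == 0L || any(!is.finite(x)))
    stop(sprintf("%s must be a nonempty finite numeric vector", what),
         call. = FALSE)
  as.numeric(x)
}

#' Dynamic time warping distance
#'
#' Standard DTW dynamic program:
#' `D(i,j) = cost(a_i, b_j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1))` with
#' `D(0,0) = 0`; the distance is `D(n,m)`, square-rooted when configured.
#' Unequal lengths are allowed.
#'
#' @param a,b Nonempty finite numeric vectors (daily percent-change series).
#' @param cfg A [dtw_config()].
#' @return Nonnegative distance; 0 iff an optimal warping path has zero cost.
#' @export
dtw_distance <- function(a, b, cfg = dtw_config()) {
  a <- check_series_arg(a, "a")
  b <- check_series_arg(b, "b")
  d <- dtw_dist_cpp(a, b, cfg_cost_type(cfg), cfg$window %||% -1L,
                    cfg$final_sqrt)
  if (!is.finite(d))
    stop("no feasible warping path: window narrower than the length difference",
         call. = FALSE)
  d
}

as_value_list <- function(series) {
  lapply(series, function(s) {
    if (inherits(s, "daily_series")) s$values
    else check_series_arg(s, "series element")
  })
}

#' Pairwise DTW distance matrix
#'
#' @param series Nonempty list of numeric vectors or [daily_series] objects.
#' @param cfg A [dtw_config()].
#' @return Symmetric matrix with zero diagonal; entry (i, j) equals
#'   `dtw_distance(series[[i]], series[[j]], cfg)`.
#' @export
dtw_distance_matrix <- function(series, cfg = dtw_config()) {
  stopifnot(length(series) >= 1L)
  xs <- as_value_list(series)
  m <- dtw_pairwise_cpp(xs, cfg_cost_type(cfg), cfg$window %||% -1L,
                        cfg$final_sqrt)
  if (any(!is.finite(m)))
    stop("no feasible warping path for some pair under the configured window",
         call. = FALSE)
  m
}

# Cross-distance matrix between two lists of series (rows = xs, cols = ys).
dtw_cross <- function(xs, ys, cfg = dtw_config()) {
  dtw_cross_cpp(as_value_list(xs), as_value_list(ys), cfg_cost_type(cfg),
                cfg$window %||% -1L, cfg$final_sqrt)
}
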