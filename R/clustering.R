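FIVE_CLASSES <- c("high_loss", "moderate_loss", "insufficient_loss",
                  "low_gain", "high_gain")
THREE_CLASSES <- c("loss", "insufficient_loss", "gain")

#' Class schemes for the weight-change outcome
#'
#' The five-class scheme distinguishes high/moderate/insufficient weight loss
#' and low/high weight gain; the three-class scheme merges the two loss
#' classes and the two gain classes. Classes are ordered from most loss to
#' most gain.
#'
#' @param name `"three_class"` or `"five_class"`.
#' @return An object of class `class_scheme` with elements `name`,
#'   `n_classes`, `classes` (ordered labels) and `map` (five-class label ->
#'   scheme label).
#' @export
class_scheme <- function(name = c("three_class", "five_class")) {
  name <- match.arg(name)
  if (name == "five_class") {
    map <- setNames(FIVE_CLASSES, FIVE_CLASSES)
    classes <- FIVE_CLASSES
  } else {
    map <- c(high_loss = "loss", moderate_loss = "loss",
             insufficient_loss = "insufficient_loss",
             low_gain = "gain", high_gain = "gain")
    classes <- THREE_CLASSES
  }
  structure(list(name = name, n_classes = length(classes), classes = classes,
                 map = map), class = "class_scheme")
}

#' Collapse five-class labels to a scheme
#'
#' @param label Character vector of five-class labels.
#' @param scheme A [class_scheme()].
#' @return Scheme labels (character).
#' @export
collapse_classes <- function(label, scheme) {
  label <- as.character(label)
  if (!all(label %in% FIVE_CLASSES))
    stop("unknown five-class label: ",
         paste(setdiff(label, FIVE_CLASSES), collapse = ", "), call. = FALSE)
  unname(scheme$map[label])
}

#' Weight-change cluster model
#'
#' Five mean daily percent-change trajectories (days 0-270) defining the
#' outcome classes, plus the regression-to-class cutoff percentages for both
#' schemes.
#'
#' @param means Numeric matrix, 271 rows (days 0-270) by 5 columns, ordered
#'   and named `high_loss` ... `high_gain`.
#' @param five_class_cutoffs,three_class_cutoffs Strictly increasing cutoff
#'   percentages (4 and 2 values).
#' @param dtw_cfg The [dtw_config()] the model was built with.
#' @param consensus_fraction,assignments,objective Optional provenance from
#'   [derive_cluster_model()].
#' @return An object of class `cluster_model`.
#' @export
cluster_model <- function(means, five_class_cutoffs, three_class_cutoffs,
                          dtw_cfg = dtw_config(), consensus_fraction = NA_real_,
                          assignments = NULL, objective = NULL) {
  means <- as.matrix(means)
  if (nrow(means) != 271L || ncol(means) != 5L)
    stop("means must be a 271 x 5 matrix (days 0-270, five classes)",
         call. = FALSE)
  if (any(!is.finite(means))) stop("cluster means must be finite", call. = FALSE)
  colnames(means) <- FIVE_CLASSES
  if (length(five_class_cutoffs) != 4L || any(diff(five_class_cutoffs) <= 0))
    stop("five_class_cutoffs must be 4 strictly increasing values",
         call. = FALSE)
  if (length(three_class_cutoffs) != 2L || any(diff(three_class_cutoffs) <= 0))
    stop("three_class_cutoffs must be 2 strictly increasing values",
         call. = FALSE)
  structure(list(means = means, class_names = FIVE_CLASSES,
                 five_class_cutoffs = as.numeric(five_class_cutoffs),
                 three_class_cutoffs = as.numeric(three_class_cutoffs),
                 dtw_cfg = dtw_cfg, consensus_fraction = consensus_fraction,
                 assignments = assignments, objective = objective),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> 5 mean trajectories, days 0-270\n")
  cat(sprintf("  terminal values: %s\n",
              paste(sprintf("%s %+.1f%%", x$class_names, x$means[271, ]),
                    collapse = ", ")))
  cat(sprintf("  five-class cutoffs: %s\n",
              paste(sprintf("%+.1f", x$five_class_cutoffs), collapse = ", ")))
  cat(sprintf("  three-class cutoffs: %s\n",
              paste(sprintf("%+.1f", x$three_class_cutoffs), collapse = ", ")))
  if (!is.na(x$consensus_fraction))
    cat(sprintf("  consensus fraction: %.1f%%\n", 100 * x$consensus_fraction))
  invisible(x)
}

#' @export
plot.cluster_model <- function(x, ...) {
  graphics::matplot(0:270, x$means, type = "l", lty = 1, lwd = 2,
                    xlab = "Day", ylab = "Weight change (%)",
                    main = "Mean weight change of the five clusters", ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  graphics::legend("bottomleft", legend = colnames(x$means), lty = 1, lwd = 2,
                   col = seq_len(5), bty = "n", cex = 0.8)
  invisible(x)
}

#' Cutoff percentages shipped with the original framework
#'
#' Regression-to-class cutoffs reported for the original training cohort,
#' usable when no training data are at hand; retraining regenerates
#' cohort-specific values.
#'
#' @param scheme A [class_scheme()].
#' @return Numeric cutoff vector (percent weight change).
#' @export
default_cutoffs <- function(scheme = class_scheme("five_class")) {
  if (scheme$name == "five_class") c(-9.2, -2.4, -0.1, 2.2)
  else c(-2.4, -0.1)
}

# Relabel `other` so its cluster indices line up with `ref` by maximal
# overlap (exact assignment via permutation enumeration, k <= 8).
match_partition <- function(ref, other, k) {
  tab <- table(factor(other, levels = seq_len(k)),
               factor(ref, levels = seq_len(k)))
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) sum(tab[cbind(seq_len(k), p)]),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  best[other]
}

#' Consensus initial centroids from multiple hierarchical clusterings
#'
#' Runs agglomerative hierarchical clustering on the DTW distance matrix
#' under several linkage criteria, label-matches the resulting partitions by
#' maximal overlap, and averages (per day) only the individuals on which all
#' variants agree. The per-cluster daily means serve as initial centroids
#' for [dtw_kmeans()].
#'
#' @param cohort_series List of [daily_series] (all spanning days 0-270) or
#'   numeric vectors of length 271.
#' @param k Number of clusters (>= 2).
#' @param variants At least two `stats::hclust` linkage methods.
#' @param cfg A [dtw_config()].
#' @return List with `centroids` (k x 271 matrix), `consensus_fraction`,
#'   `labels` (reference-variant labels) and `consensual` (logical).
#' @export
consensus_initial_centroids <- function(cohort_series, k = 5L,
                                        variants = c("average", "complete",
                                                     "ward.D2"),
                                        cfg = dtw_config()) {
  stopifnot(k >= 2L, length(variants) >= 2L)
  vals <- as_value_list(cohort_series)
  lens <- lengths(vals)
  if (any(lens != 271L))
    stop("all series must span days 0-270 (271 values)", call. = FALSE)
  V <- do.call(rbind, vals)
  D <- dtw_distance_matrix(cohort_series, cfg)
  labs <- lapply(variants, function(m)
    stats::cutree(stats::hclust(stats::as.dist(D), method = m), k = k))
  consensus_core(labs, V, k)
}

# Label-match a list of k-clusterings to the first one and average the
# consensual members per cluster.
consensus_core <- function(labs, V, k) {
  ref <- labs[[1]]
  matched <- lapply(labs[-1], match_partition, ref = ref, k = k)
  agree <- Reduce(`&`, lapply(matched, function(l) l == ref),
                  init = rep(TRUE, length(ref)))
  centroids <- matrix(NA_real_, nrow = k, ncol = ncol(V))
  for (c in seq_len(k)) {
    members <- agree & ref == c
    if (!any(members))
      stop(sprintf("degenerate consensus: cluster %d has no consensual members", c),
           call. = FALSE)
    centroids[c, ] <- colMeans(V[members, , drop = FALSE])
  }
  list(centroids = centroids, consensus_fraction = mean(agree),
       labels = ref, consensual = agree)
}

#' k-means with DTW assignment on daily series
#'
#' Lloyd iterations with DTW as the assignment distance and the arithmetic
#' per-day mean of the assigned series as the centroid update (all series
#' share the daily grid). Iterates until assignments are unchanged or
#' `max_iter` is reached; ties go to the lowest cluster index; an empty
#' cluster keeps its previous centroid (with a warning).
#'
#' @param cohort_series List of series, all the same length as the centroids.
#' @param init_centroids k x L numeric matrix of initial centroids.
#' @param cfg A [dtw_config()].
#' @param max_iter Iteration cap.
#' @return List with `means` (k x L), `assignments`, `objective` (sum of
#'   member-to-centroid DTW distances, one value per iteration) and
#'   `iterations`.
#' @export
dtw_kmeans <- function(cohort_series, init_centroids, cfg = dtw_config(),
                       max_iter = 100L) {
  vals <- as_value_list(cohort_series)
  C <- as.matrix(init_centroids)
  if (any(lengths(vals) != ncol(C)))
    stop("centroids must have the same length as the series", call. = FALSE)
  n <- length(vals)
  k <- nrow(C)
  assign_prev <- rep(NA_integer_, n)
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    d <- dtw_cross(vals, asplit(C, 1), cfg)
    assignment <- max.col(-d, ties.method = "first")
    objective <- c(objective, sum(d[cbind(seq_len(n), assignment)]))
    if (identical(assignment, assign_prev)) break
    assign_prev <- assignment
    for (c in seq_len(k)) {
      members <- assignment == c
      if (!any(members)) {
        warning(sprintf("cluster %d empty at iteration %d; keeping previous centroid",
                        c, it), call. = FALSE)
        next
      }
      C[c, ] <- colMeans(do.call(rbind, vals[members]))
    }
  }
  list(means = C, assignments = assign_prev, objective = objective,
       iterations = length(objective))
}

#' Optimize regression-to-class cutoffs
#'
#' For each adjacent pair of classes (ordered most loss first), the boundary
#' is chosen among the observed 9-month weight-change values of the members
#' of those two classes: a value `v` classifies `x` as the lower (more-loss)
#' class iff `x <= v`; the cutoff minimizing the number of classification
#' errors is selected, and among ties the largest value is returned.
#'
#' @param observed_9mo Observed percent weight change at day 270, one per
#'   individual.
#' @param labels Class label per individual.
#' @param classes Ordered class labels (most loss first); defaults to the
#'   scheme order implied by the labels' scheme.
#' @return Cutoff vector of length `length(classes) - 1`.
#' @export
optimize_cutoffs <- function(observed_9mo, labels, classes = NULL) {
  labels <- as.character(labels)
  stopifnot(length(observed_9mo) == length(labels))
  if (is.null(classes)) {
    classes <- if (all(labels %in% THREE_CLASSES) &&
                   !all(labels %in% FIVE_CLASSES)) THREE_CLASSES
               else FIVE_CLASSES
  }
  if (inherits(classes, "class_scheme")) classes <- classes$classes
  missing <- setdiff(classes, labels)
  if (length(missing))
    stop("class with no members: ", paste(missing, collapse = ", "),
         call. = FALSE)
  vapply(seq_len(length(classes) - 1L), function(i) {
    lower <- classes[i]; upper <- classes[i + 1L]
    sel <- labels %in% c(lower, upper)
    x <- observed_9mo[sel]; l <- labels[sel]
    cand <- sort(unique(x))
    errs <- vapply(cand, function(v)
      sum(x <= v & l == upper) + sum(x > v & l == lower), numeric(1))
    max(cand[errs == min(errs)])
  }, numeric(1))
}

#' Assign a series to its nearest cluster by DTW
#'
#' @param series A [daily_series] or numeric vector.
#' @param model A [cluster_model()].
#' @param frame_end Optional day; cluster means are truncated to days
#'   0..`frame_end` before comparison (used for frame-limited input).
#' @return Five-class label (character); attribute `"distances"` carries the
#'   DTW distances to the five means. Ties go to the lower class index.
#' @export
assign_class_by_dtw <- function(series, model, frame_end = NULL) {
  v <- as_value_list(list(series))[[1]]
  M <- model$means
  if (!is.null(frame_end)) {
    stopifnot(frame_end >= 0L, frame_end <= 270L)
    M <- M[1:(frame_end + 1L), , drop = FALSE]
  }
  d <- vapply(seq_len(ncol(M)), function(c)
    dtw_distance(v, M[, c], model$dtw_cfg), numeric(1))
  lab <- model$class_names[which.min(d)]
  attr(lab, "distances") <- setNames(d, model$class_names)
  lab
}

#' Derive the weight-change cluster model from a training cohort
#'
#' Full class-definition pipeline: DTW distance matrix; agglomerative
#' clustering under several linkage criteria; consensus centroids from the
#' individuals all variants agree on; DTW k-means refinement over the whole
#' cohort; ordering of the final clusters by their day-270 mean value
#' (most loss first) to name the five classes; and cutoff optimization for
#' the five- and three-class schemes from the observed day-270 values.
#'
#' @param cohort List of [participant_record] objects (post-exclusion; all
#'   must reach day 270 after interpolation/extrapolation).
#' @param variants Linkage criteria for the consensus step.
#' @param cfg A [dtw_config()].
#' @param max_iter k-means iteration cap.
#' @return A [cluster_model()]; `assignments` holds the five-class label per
#'   cohort member, `objective` the k-means objective trace.
#' @export
derive_cluster_model <- function(cohort,
                                 variants = c("average", "complete", "ward.D2"),
                                 cfg = dtw_config(), max_iter = 100L) {
  series <- lapply(cohort, function(r)
    extrapolate_to(percent_change_series(r), 270L))
  cons <- consensus_initial_centroids(series, k = 5L, variants = variants,
                                      cfg = cfg)
  km <- dtw_kmeans(series, cons$centroids, cfg = cfg, max_iter = max_iter)
  ord <- order(km$means[, 271L])                # most loss -> most gain
  means <- t(km$means[ord, , drop = FALSE])     # 271 x 5
  relabel <- match(km$assignments, ord)         # cluster index in class order
  labels5 <- FIVE_CLASSES[relabel]
  y270 <- vapply(series, function(s) s$values[271L], numeric(1))
  cut5 <- optimize_cutoffs(y270, labels5, FIVE_CLASSES)
  labels3 <- collapse_classes(labels5, class_scheme("three_class"))
  cut3 <- optimize_cutoffs(y270, labels3, THREE_CLASSES)
  if (any(diff(cut5) <= 0) || any(diff(cut3) <= 0))
    stop("optimized cutoffs are not strictly increasing; classes overlap too much",
         call. = FALSE)
  cluster_model(means, cut5, cut3, dtw_cfg = cfg,
                consensus_fraction = cons$consensus_fraction,
                assignments = setNames(labels5,
                                       vapply(cohort, `[[`, character(1), "id")),
                objective = km$objective)
}

#' Serialize / restore a cluster model as JSON
#'
#' @param model A [cluster_model()].
#' @param path Output (input) file path.
#' @return `write_cluster_model` invisibly returns `path`;
#'   `read_cluster_model` returns the restored [cluster_model()].
#' @export
write_cluster_model <- function(model, path) {
  obj <- list(class_names = model$class_names,
              means = unname(as.data.frame(model$means)),
              five_class_cutoffs = model$five_class_cutoffs,
              three_class_cutoffs = model$three_class_cutoffs,
              dtw_cfg = list(local_cost = model$dtw_cfg$local_cost,
                             window = model$dtw_cfg$window,
                             final_sqrt = model$dtw_cfg$final_sqrt),
              consensus_fraction = model$consensus_fraction)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  means <- obj$means
  if (is.list(means)) means <- do.call(cbind, lapply(means, as.numeric))
  means <- matrix(as.numeric(means), nrow = 271L)
  cfg <- dtw_config(local_cost = obj$dtw_cfg$local_cost,
                    window = obj$dtw_cfg$window,
                    final_sqrt = obj$dtw_cfg$final_sqrt)
  cluster_model(means, obj$five_class_cutoffs, obj$three_class_cutoffs,
                dtw_cfg = cfg,
                consensus_fraction = obj$consensus_fraction %||% NA_real_)
}
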