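#' Confusion matrix
#'
#' Rows are truth, columns are prediction, with the class order fixed by the
#' scheme.
#'
#' @param truth,predictions Class label vectors of equal length.
#' @param scheme A [class_scheme()] (or an ordered character vector of
#'   classes).
#' @return Integer k x k matrix.
#' @export
confusion_matrix <- function(truth, predictions, scheme) {
  classes <- if (inherits(scheme, "class_scheme")) scheme$classes else scheme
  if (length(truth) != length(predictions))
    stop("truth and predictions must have equal length", call. = FALSE)
  m <- unclass(table(factor(truth, levels = classes),
                     factor(predictions, levels = classes)))
  names(dimnames(m)) <- NULL
  m
}

#' Evaluate class predictions
#'
#' Accuracy is the fraction of predictions matching the truth. Per-class
#' one-vs-rest metrics: sensitivity TP/(TP+FN), specificity TN/(TN+FP),
#' precision TP/(TP+FP) and the F1 harmonic mean. Precision and F1 are
#' reported as `NA` (undefined), not zero, when a class is never predicted.
#'
#' @param predictions,truth Equal-length nonempty class label vectors.
#' @param scheme A [class_scheme()].
#' @param random_baseline Optional baseline accuracy to carry in the report.
#' @return An object of class `eval_report` with `accuracy`, `per_class`
#'   (data frame), `confusion`, `n` and `random_baseline`.
#' @export
evaluate <- function(predictions, truth, scheme, random_baseline = NA_real_) {
  if (length(predictions) != length(truth) || length(truth) == 0L)
    stop("predictions and truth must be nonempty and of equal length",
         call. = FALSE)
  cm <- confusion_matrix(truth, predictions, scheme)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  classes <- if (inherits(scheme, "class_scheme")) scheme$classes else scheme
  per_class <- do.call(rbind, lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- n - tp - fn - fp
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0)
      2 * prec * sens / (prec + sens) else NA_real_
    data.frame(class = classes[i], sensitivity = sens, specificity = spec,
               precision = prec, f1 = f1, stringsAsFactors = FALSE)
  }))
  structure(list(accuracy = acc, per_class = per_class, confusion = cm,
                 n = n, random_baseline = random_baseline),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy = %.3f", x$n, x$accuracy))
  if (!is.na(x$random_baseline))
    cat(sprintf(" (random baseline %.3f)", x$random_baseline))
  cat("\nPer-class metrics:\n")
  print(x$per_class, row.names = FALSE, digits = 3)
  cat("Confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Collapse a five-class confusion matrix to the three-class scheme
#'
#' @param cm Five-class confusion matrix (rows/cols in five-class order).
#' @return Three-class confusion matrix; identical to evaluating collapsed
#'   predictions directly.
#' @export
collapse_confusion <- function(cm) {
  scheme <- class_scheme("three_class")
  map <- scheme$map[rownames(cm) %||% FIVE_CLASSES]
  g <- factor(map, levels = scheme$classes)
  out <- t(rowsum(t(rowsum(cm, g)), g))   # rows = truth groups, cols = pred
  m <- as.matrix(out)[scheme$classes, scheme$classes]
  storage.mode(m) <- "integer"
  m
}

#' Random-prediction baseline accuracy
#'
#' Draws, for each validation individual independently, a class from the
#' training-cohort class distribution, scores the accuracy against the
#' truth, and averages over `n_rep` replicates. Converges to
#' `sum_c p_train(c) * p_truth(c)`.
#'
#' @param train_class_probs Named probability vector over the classes
#'   (sums to 1).
#' @param truth Class label per validation individual.
#' @param n_rep Number of replicates (>= 1).
#' @param seed Integer seed.
#' @return Mean accuracy over replicates.
#' @export
random_baseline <- function(train_class_probs, truth, n_rep = 10000L,
                            seed = 1L) {
  if (abs(sum(train_class_probs) - 1) > 1e-8)
    stop("class probabilities must sum to 1", call. = FALSE)
  stopifnot(n_rep >= 1L)
  classes <- names(train_class_probs)
  if (is.null(classes)) classes <- as.character(seq_along(train_class_probs))
  n <- length(truth)
  truth <- as.character(truth)
  withr::with_seed(seed, {
    draws <- matrix(sample(classes, n * n_rep, replace = TRUE,
                           prob = train_class_probs),
                    nrow = n_rep, byrow = TRUE)
    mean(rowMeans(draws == matrix(truth, nrow = n_rep, ncol = n, byrow = TRUE)))
  })
}
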