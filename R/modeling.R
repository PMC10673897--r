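#' Supervised methods and their default input encodings
#'
#' Six supervised learners are supported: multinomial logistic regression,
#' linear regression, Gaussian naive Bayes, support vector classification,
#' support vector regression, and a single-hidden-layer perceptron. The
#' default input encoding per method is the one that performed best for the
#' original framework: DTW distances to the five cluster means for the
#' logistic, linear and support-vector-classification models; baseline BMI
#' plus the frame-end weight change for naive Bayes, support vector
#' regression and the perceptron.
#'
#' @return `all_methods()`: character vector of method names;
#'   `default_encodings()`: named character vector method -> encoding.
#' @export
all_methods <- function() {
  c("logistic_regression", "linear_regression", "naive_bayes",
    "support_vector_classification", "support_vector_regression",
    "multilayer_perceptron")
}

#' @rdname all_methods
#' @export
default_encodings <- function() {
  c(logistic_regression = "dtw_dists",
    linear_regression = "dtw_dists",
    naive_bayes = "bmi_last",
    support_vector_classification = "dtw_dists",
    support_vector_regression = "bmi_last",
    multilayer_perceptron = "bmi_last")
}

regression_methods <- function() {
  c("linear_regression", "support_vector_regression")
}

#' Training control parameters
#'
#' @param seed Master seed for fold assignment and perceptron
#'   initialization.
#' @param n_folds Cross-validation folds.
#' @param logistic_decay,mlp_decay L2 weight decay for the multinomial
#'   logistic model and the perceptron.
#' @param mlp_maxit,mlp_size Perceptron optimizer iterations and hidden
#'   layer size (`NULL` = twice the input length).
#' @param svm_cost Soft-margin cost for the RBF support vector machines.
#' @param select_encoding If `TRUE`, re-select each method's input encoding
#'   as the one maximizing mean cross-validated accuracy (instead of the
#'   shipped defaults).
#' @param max_iter_kmeans Iteration cap when the cluster model is derived.
#' @return An object of class `wtraj_control`.
#' @export
wtraj_control <- function(seed = 1L, n_folds = 5L, logistic_decay = 0.01,
                          mlp_decay = 0.01, mlp_maxit = 300L, mlp_size = NULL,
                          svm_cost = 1, select_encoding = FALSE,
                          max_iter_kmeans = 100L) {
  structure(list(seed = as.integer(seed), n_folds = as.integer(n_folds),
                 logistic_decay = logistic_decay, mlp_decay = mlp_decay,
                 mlp_maxit = mlp_maxit, mlp_size = mlp_size,
                 svm_cost = svm_cost,
                 select_encoding = isTRUE(select_encoding),
                 max_iter_kmeans = max_iter_kmeans),
            class = "wtraj_control")
}

#' Build the input feature vector for one individual
#'
#' Encodings: `"bmi_last"` = baseline BMI and the weight change at the last
#' day of the frame; `"bmi_history"` = baseline BMI and the weight change at
#' the end of each grid frame up to the current one; `"dtw_dists"` = DTW
#' distances between the observed series and the five cluster means
#' (truncated to the frame); `"daily"` = baseline BMI and the daily weight
#' changes of days 1..frame end (perceptron only).
#'
#' @param series A [daily_series] restricted/extrapolated to the frame.
#' @param rec The corresponding [participant_record] (supplies height).
#' @param frame A [time_frame()].
#' @param encoding One of `"bmi_last"`, `"bmi_history"`, `"dtw_dists"`,
#'   `"daily"`.
#' @param model A [cluster_model()] (needed for `"dtw_dists"`).
#' @return Named numeric feature vector.
#' @export
build_features <- function(series, rec, frame, encoding, model = NULL) {
  stopifnot(inherits(frame, "time_frame"))
  if (length(series$values) != frame$end_day + 1L)
    stop("series must be restricted to the time frame before encoding",
         call. = FALSE)
  b0 <- bmi(series$baseline_weight, rec$height_cm)
  switch(encoding,
    bmi_last = c(bmi0 = b0, last = series$values[frame$end_day + 1L]),
    bmi_history = {
      ends <- frame_grid_ends()
      ends <- ends[ends <= frame$end_day]
      c(bmi0 = b0, setNames(series$values[ends + 1L], paste0("d", ends)))
    },
    dtw_dists = {
      if (is.null(model))
        stop("encoding 'dtw_dists' requires a cluster model", call. = FALSE)
      lab <- assign_class_by_dtw(series, model, frame_end = frame$end_day)
      attr(lab, "distances")
    },
    daily = c(bmi0 = b0,
              setNames(series$values[-1L], paste0("d", seq_len(frame$end_day)))),
    stop(sprintf("unknown encoding '%s'", encoding), call. = FALSE))
}

#' Class-stratified cross-validation folds
#'
#' Within each class, members are shuffled (seeded) and `floor(n_c/n_folds)`
#' are dealt to every fold; remainders are distributed round-robin starting
#' at the first fold. Every individual is assigned exactly once.
#'
#' @param labels Class label per individual.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold index (1..n_folds) per individual.
#' @export
stratified_folds <- function(labels, n_folds = 5L, seed = 1L) {
  labels <- as.character(labels)
  n_folds <- as.integer(n_folds)
  counts <- table(labels)
  if (any(counts < n_folds))
    stop("stratification error: class smaller than the number of folds: ",
         paste(names(counts)[counts < n_folds], collapse = ", "),
         call. = FALSE)
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- sample(which(labels == cl))
      base <- length(idx) %/% n_folds
      r <- length(idx) %% n_folds
      assign <- c(rep(seq_len(n_folds), each = base),
                  if (r > 0) seq_len(r))
      folds[idx] <- assign
    }
  })
  folds
}

standardizer <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

apply_standardizer <- function(X, sc) {
  scale(X, center = sc$center, scale = sc$scale)
}

as_model_df <- function(X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df
}

fit_learner <- function(method, X, y, control, seed) {
  scaler <- NULL
  df <- as_model_df(X)
  fit <- switch(method,
    logistic_regression = {
      scaler <- standardizer(X)
      df <- as_model_df(apply_standardizer(X, scaler))
      df$.y <- y
      nnet::multinom(.y ~ ., data = df, decay = control$logistic_decay,
                     trace = FALSE, maxit = 500)
    },
    linear_regression = {
      df$.y <- y
      stats::lm(.y ~ ., data = df)
    },
    naive_bayes = e1071::naiveBayes(df, y),
    support_vector_classification = {
      e1071::svm(x = X, y = y, type = "C-classification", kernel = "radial",
                 cost = control$svm_cost,
                 scale = apply(X, 2, stats::sd) > 0)
    },
    support_vector_regression = {
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                 cost = control$svm_cost,
                 scale = apply(X, 2, stats::sd) > 0)
    },
    multilayer_perceptron = {
      scaler <- standardizer(X)
      df <- as_model_df(apply_standardizer(X, scaler))
      df$.y <- y
      size <- control$mlp_size %||% (2L * ncol(X))
      withr::with_seed(seed,
        nnet::nnet(.y ~ ., data = df, size = size, decay = control$mlp_decay,
                   maxit = control$mlp_maxit, trace = FALSE, MaxNWts = 20000))
    },
    stop(sprintf("unknown method '%s'", method), call. = FALSE))
  list(fit = fit, scaler = scaler)
}

predict_learner <- function(method, learner, X, classes = NULL) {
  Xs <- if (!is.null(learner$scaler)) apply_standardizer(X, learner$scaler) else X
  df <- as_model_df(Xs)
  switch(method,
    logistic_regression = {
      cls <- as.character(predict(learner$fit, newdata = df, type = "class"))
      pr <- predict(learner$fit, newdata = df, type = "probs")
      if (is.null(dim(pr))) {
        if (nrow(df) == 1L) {
          pr <- matrix(pr, nrow = 1, dimnames = list(NULL, names(pr)))
        } else {
          # two-level fit: vector of P(second level)
          pr <- cbind(1 - pr, pr)
          colnames(pr) <- learner$fit$lev
        }
      }
      list(class = cls, prob = pr)
    },
    linear_regression = list(value = unname(predict(learner$fit, newdata = df))),
    naive_bayes = list(
      class = as.character(predict(learner$fit, df, type = "class")),
      prob = predict(learner$fit, df, type = "raw")),
    support_vector_classification =
      list(class = as.character(predict(learner$fit, X))),
    support_vector_regression =
      list(value = unname(predict(learner$fit, X))),
    multilayer_perceptron = {
      pr <- predict(learner$fit, newdata = df, type = "raw")
      cls <- as.character(predict(learner$fit, newdata = df, type = "class"))
      list(class = cls, prob = pr)
    })
}

#' Convert a regression-predicted percent change to a class
#'
#' Classes are ordered most loss first; a prediction `x` falls in class `i`
#' when `cutoff[i-1] < x <= cutoff[i]` (a value exactly on a cutoff belongs
#' to the lower, more-loss class, matching [optimize_cutoffs()]).
#'
#' @param prediction Predicted percent weight change (vectorized).
#' @param cutoffs Strictly increasing cutoff vector, one fewer than classes.
#' @param scheme A [class_scheme()].
#' @return Class label(s).
#' @export
regression_to_class <- function(prediction, cutoffs, scheme) {
  stopifnot(length(cutoffs) == scheme$n_classes - 1L)
  # values within rounding error of a cutoff count as on it (lower class)
  tol <- 1e-8 * pmax(1, abs(cutoffs))
  idx <- vapply(prediction, function(p) sum(p > cutoffs + tol) + 1L,
                integer(1))
  scheme$classes[idx]
}

#' Select the prediction time frame closest to the observed data
#'
#' @param last_observed_day Day of the individual's last weight entry.
#' @param grid List of [time_frame()]s (defaults to the nine-frame grid).
#' @return The frame minimizing `|end_day - last_observed_day|`; ties go to
#'   the larger frame (three and a half months of data select the 4-month
#'   frame).
#' @export
select_frame <- function(last_observed_day, grid = time_frames()) {
  stopifnot(last_observed_day >= 1L)
  ends <- vapply(grid, `[[`, integer(1), "end_day")
  d <- abs(ends - last_observed_day)
  cand <- which(d == min(d))
  grid[[cand[which.max(ends[cand])]]]
}

#' Check prediction eligibility for a time frame
#'
#' Two rules gate a prediction: at least two weight entries within the
#' frame, and the last in-frame entry no more than 30 days before the frame
#' end.
#'
#' @param rec A [participant_record].
#' @param frame A [time_frame()].
#' @return List with `eligible` (logical) and `reasons` (character,
#'   violated rules).
#' @export
check_eligibility <- function(rec, frame) {
  d <- rec$entries$day[rec$entries$day <= frame$end_day]
  reasons <- character(0)
  if (length(d) < 2L)
    reasons <- c(reasons, "fewer than two entries within the time frame")
  if (length(d) == 0L || max(d) < frame$end_day - 30L)
    reasons <- c(reasons, "last entry more than 30 days before the frame end")
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

# Internal: cross-validated accuracy and final fit for one
# (method, scheme, frame) cell. X rows align with labels/y270.
fit_cell <- function(method, X, labels, y270, scheme, folds, control, seed) {
  is_reg <- method %in% regression_methods()
  classes <- scheme$classes
  yfac <- factor(labels, levels = classes)
  n <- nrow(X)
  correct <- logical(n)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (is_reg) {
      lrn <- fit_learner(method, X[tr, , drop = FALSE], y270[tr], control,
                         seed + f)
      # conversion cutoffs calibrated on the training-fold predictions
      fitted_tr <- predict_learner(method, lrn, X[tr, , drop = FALSE])$value
      cuts <- optimize_cutoffs(fitted_tr, labels[tr], classes)
      pred <- regression_to_class(
        predict_learner(method, lrn, X[!tr, , drop = FALSE])$value,
        cuts, scheme)
    } else {
      lrn <- fit_learner(method, X[tr, , drop = FALSE],
                         droplevels(yfac[tr]), control, seed + f)
      pred <- predict_learner(method, lrn, X[!tr, , drop = FALSE], classes)$class
    }
    correct[!tr] <- pred == labels[!tr]
  }
  cv_accuracy <- mean(correct)
  if (is_reg) {
    learner <- fit_learner(method, X, y270, control, seed)
    fitted_all <- predict_learner(method, learner, X)$value
    cutoffs <- optimize_cutoffs(fitted_all, labels, classes)
  } else {
    learner <- fit_learner(method, X, yfac, control, seed)
    cutoffs <- NULL
  }
  list(cv_accuracy = cv_accuracy, learner = learner, cutoffs = cutoffs)
}

#' Fit the weight-change prediction framework
#'
#' The single training entry point. Screens the cohort with the exclusion
#' criteria, derives (or accepts) the five-cluster outcome model, labels
#' every individual by nearest-cluster DTW assignment, and trains one model
#' per (method, class scheme, time frame) cell with class-stratified
#' fivefold cross-validation. Regression-type methods predict the 9-month
#' percent weight change and are converted to classes with cutoffs
#' optimized on the observed training values.
#'
#' @param cohort List of [participant_record] objects.
#' @param methods Subset of [all_methods()].
#' @param schemes Character vector among `"three_class"`, `"five_class"`.
#' @param frames List of [time_frame()]s (default: all nine).
#' @param cluster_model Optional pre-built [cluster_model()]; derived from
#'   the cohort when `NULL`.
#' @param exclusions An [exclusion_config()] applied before training.
#' @param control A [wtraj_control()].
#' @return An object of class `wtraj_fit` with elements `cluster_model`,
#'   `models` (nested method/scheme/frame list), `cv_accuracy` (data frame),
#'   `labels` (per-individual truth per scheme), `encodings`, `exclusion_log`
#'   and `n`.
#' @seealso [predict.wtraj_fit()], [predict_individual()]
#' @export
wtraj_fit <- function(cohort, methods = all_methods(),
                      schemes = c("three_class", "five_class"),
                      frames = time_frames(), cluster_model = NULL,
                      exclusions = exclusion_config(),
                      control = wtraj_control()) {
  stopifnot(all(methods %in% all_methods()),
            all(schemes %in% c("three_class", "five_class")))
  scr <- apply_exclusions(cohort, exclusions)
  cohort <- scr$kept
  if (length(cohort) < 2L)
    stop("fewer than two participants remain after exclusions", call. = FALSE)

  series270 <- lapply(cohort, function(r)
    extrapolate_to(percent_change_series(r), 270L))
  if (is.null(cluster_model))
    cluster_model <- derive_cluster_model(cohort, cfg = dtw_config(),
                                          max_iter = control$max_iter_kmeans)
  labels5 <- vapply(series270, function(s)
    as.character(assign_class_by_dtw(s, cluster_model)), character(1))
  missing <- setdiff(FIVE_CLASSES, labels5)
  if (length(missing))
    stop("training error: no individuals in class ",
         paste(missing, collapse = ", "), call. = FALSE)
  y270 <- vapply(series270, function(s) s$values[271L], numeric(1))

  scheme_objs <- lapply(schemes, class_scheme)
  names(scheme_objs) <- schemes
  labels <- lapply(scheme_objs, function(s) collapse_classes(labels5, s))
  folds <- lapply(seq_along(schemes), function(i)
    stratified_folds(labels[[i]], control$n_folds, control$seed + i))
  names(folds) <- schemes

  frame_series_list <- lapply(frames, function(fr)
    lapply(series270, restrict_to_frame, frame = fr))

  feature_cache <- new.env(parent = emptyenv())
  get_features <- function(fi, encoding) {
    key <- paste0(encoding, "@", fi)
    if (is.null(feature_cache[[key]])) {
      fr <- frames[[fi]]
      feature_cache[[key]] <- do.call(rbind, Map(function(s, r)
        build_features(s, r, fr, encoding, cluster_model),
        frame_series_list[[fi]], cohort))
    }
    feature_cache[[key]]
  }

  encodings <- default_encodings()[methods]
  cv_rows <- list()
  models <- list()
  cell_seed <- function(mi, si, fi) {
    control$seed + 1000L * mi + 100L * si + 10L * fi
  }

  run_method <- function(method, encoding, keep_models) {
    mi <- match(method, all_methods())
    out_models <- list()
    rows <- list()
    for (si in seq_along(schemes)) {
      sch <- scheme_objs[[si]]
      for (fi in seq_along(frames)) {
        fr <- frames[[fi]]
        X <- get_features(fi, encoding)
        cell <- fit_cell(method, X, labels[[si]], y270, sch, folds[[si]],
                         control, cell_seed(mi, si, fi))
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, scheme = sch$name, frame = fr$label,
          months = fr$months, encoding = encoding,
          cv_accuracy = cell$cv_accuracy, stringsAsFactors = FALSE)
        if (keep_models) {
          out_models[[sch$name]][[fr$label]] <- structure(
            list(method = method, frame = fr, scheme = sch,
                 encoding = encoding, learner = cell$learner,
                 cutoffs = cell$cutoffs, cv_accuracy = cell$cv_accuracy),
            class = "trained_frame_model")
        }
      }
    }
    list(models = out_models, rows = rows)
  }

  for (method in methods) {
    encoding <- encodings[[method]]
    if (control$select_encoding) {
      cand <- c("bmi_last", "bmi_history", "dtw_dists")
      if (method == "multilayer_perceptron") cand <- c(cand, "daily")
      mean_acc <- vapply(cand, function(enc) {
        res <- run_method(method, enc, keep_models = FALSE)
        mean(vapply(res$rows, `[[`, numeric(1), "cv_accuracy"))
      }, numeric(1))
      encoding <- cand[which.max(mean_acc)]
      encodings[[method]] <- encoding
    }
    res <- run_method(method, encoding, keep_models = TRUE)
    models[[method]] <- res$models
    cv_rows <- c(cv_rows, res$rows)
  }

  structure(list(cluster_model = cluster_model, models = models,
                 cv_accuracy = do.call(rbind, cv_rows),
                 labels = c(list(five_class_truth = labels5), labels),
                 encodings = encodings, schemes = schemes,
                 frames = frames, control = control,
                 exclusion_log = scr$log, n = length(cohort),
                 call = match.call()),
            class = "wtraj_fit")
}

#' @export
print.wtraj_fit <- function(x, ...) {
  cat(sprintf("<wtraj_fit> %d participants, %d method(s), schemes: %s\n",
              x$n, length(x$models), paste(x$schemes, collapse = ", ")))
  cat(sprintf("  frames: %s months\n",
              paste(vapply(x$frames, `[[`, character(1), "label"),
                    collapse = ", ")))
  agg <- stats::aggregate(cv_accuracy ~ method + scheme, data = x$cv_accuracy,
                          FUN = mean)
  cat("  mean CV accuracy across frames:\n")
  for (i in seq_len(nrow(agg)))
    cat(sprintf("    %-30s %-12s %.3f\n", agg$method[i], agg$scheme[i],
                agg$cv_accuracy[i]))
  invisible(x)
}

#' @export
summary.wtraj_fit <- function(object, ...) {
  wide <- stats::reshape(
    object$cv_accuracy[, c("method", "scheme", "frame", "cv_accuracy")],
    idvar = c("method", "scheme"), timevar = "frame", direction = "wide")
  names(wide) <- sub("^cv_accuracy\\.", "", names(wide))
  structure(list(cv = wide, cluster_model = object$cluster_model,
                 encodings = object$encodings, n = object$n),
            class = "summary.wtraj_fit")
}

#' @export
print.summary.wtraj_fit <- function(x, ...) {
  cat(sprintf("Weight-change prediction framework fitted on %d participants\n",
              x$n))
  print(x$cluster_model)
  cat("\nInput encodings:\n")
  for (m in names(x$encodings))
    cat(sprintf("  %-30s %s\n", m, x$encodings[[m]]))
  cat("\nCross-validated accuracy by time frame (months):\n")
  print(x$cv, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.wtraj_fit <- function(x, ...) plot(x$cluster_model, ...)

#' @export
coef.wtraj_fit <- function(object, method = "logistic_regression",
                           scheme = "three_class", frame = "8", ...) {
  tm <- object$models[[method]][[scheme]][[frame]]
  if (is.null(tm)) stop("no trained model for that cell", call. = FALSE)
  stats::coef(tm$learner$fit)
}

#' Predict the weight-change class for one individual
#'
#' Chooses the time frame closest to the individual's last entry, checks
#' eligibility, builds the percent-change series from the in-frame entries
#' (interpolated, then extrapolated to the frame end), encodes the features
#' for the requested method, and predicts. The five-class prediction is
#' reported only when the selected frame is longer than 4 months; the
#' three-class prediction is always reported.
#'
#' @param rec A [participant_record].
#' @param fit A [wtraj_fit] object.
#' @param method One of the trained methods.
#' @return An object of class `wtraj_prediction`: list with `id`, `frame`,
#'   `three_class`, `five_class` (or `NA`), `probabilities` (when the method
#'   provides them) and `dtw_distances` to the five cluster means.
#' @export
predict_individual <- function(rec, fit, method = "logistic_regression") {
  if (is.null(fit$models[[method]]))
    stop(sprintf("method '%s' was not trained", method), call. = FALSE)
  frame <- select_frame(max(rec$entries$day), fit$frames)
  elig <- check_eligibility(rec, frame)
  if (!elig$eligible)
    stop("individual not eligible for frame ", frame$label, " months: ",
         paste(elig$reasons, collapse = "; "), call. = FALSE)
  series <- frame_series(rec, frame)
  dists <- attr(assign_class_by_dtw(series, fit$cluster_model,
                                    frame_end = frame$end_day), "distances")
  predict_one_scheme <- function(scheme_name) {
    tm <- fit$models[[method]][[scheme_name]][[frame$label]]
    if (is.null(tm)) return(NULL)
    X <- matrix(build_features(series, rec, frame, tm$encoding,
                               fit$cluster_model), nrow = 1)
    out <- predict_learner(method, tm$learner, X, tm$scheme$classes)
    if (method %in% regression_methods()) {
      list(class = regression_to_class(out$value, tm$cutoffs, tm$scheme),
           value = out$value)
    } else {
      pr <- out$prob
      if (!is.null(pr)) {
        pr <- as.numeric(pr)
        # multinom/nnet may report k-1 or k columns depending on layout
        if (length(pr) == tm$scheme$n_classes - 1L) pr <- c(1 - sum(pr), pr)
        pr <- setNames(pr, tm$scheme$classes)
      }
      list(class = out$class, prob = pr)
    }
  }
  p3 <- predict_one_scheme("three_class")
  p5 <- if (frame$months > 4) predict_one_scheme("five_class") else NULL
  structure(list(id = rec$id, frame = frame,
                 three_class = if (!is.null(p3)) p3$class else NA_character_,
                 five_class = if (!is.null(p5)) p5$class else NA_character_,
                 probabilities = list(three_class = p3$prob,
                                      five_class = if (!is.null(p5)) p5$prob),
                 predicted_pct = list(three_class = p3$value,
                                      five_class = if (!is.null(p5)) p5$value),
                 dtw_distances = dists),
            class = "wtraj_prediction")
}

#' @export
print.wtraj_prediction <- function(x, ...) {
  cat(sprintf("<prediction %s> frame %s months: three-class = %s",
              x$id, x$frame$label, x$three_class))
  if (!is.na(x$five_class)) cat(sprintf(", five-class = %s", x$five_class))
  cat("\n")
  invisible(x)
}

#' Predict the class at a fixed time frame
#'
#' Validation-style prediction: the frame is given rather than chosen from
#' the data, eligibility for that frame is checked, and the class under the
#' requested scheme is returned. Used to score a validation cohort frame by
#' frame.
#'
#' @param rec A [participant_record].
#' @param fit A [wtraj_fit] object.
#' @param frame A [time_frame()] the bundle was trained for.
#' @param method One of the trained methods.
#' @param scheme `"three_class"` or `"five_class"`.
#' @return Class label, or `NA_character_` when the individual is not
#'   eligible for the frame (with the reasons in attribute `"reasons"`).
#' @export
predict_at_frame <- function(rec, fit, frame, method = "logistic_regression",
                             scheme = "three_class") {
  elig <- check_eligibility(rec, frame)
  if (!elig$eligible)
    return(structure(NA_character_, reasons = elig$reasons))
  tm <- fit$models[[method]][[scheme]][[frame$label]]
  if (is.null(tm))
    stop(sprintf("no trained model for %s/%s at frame %s", method, scheme,
                 frame$label), call. = FALSE)
  series <- frame_series(rec, frame)
  X <- matrix(build_features(series, rec, frame, tm$encoding,
                             fit$cluster_model), nrow = 1)
  out <- predict_learner(method, tm$learner, X, tm$scheme$classes)
  if (method %in% regression_methods())
    regression_to_class(out$value, tm$cutoffs, tm$scheme)
  else out$class
}

#' Predict weight-change classes for new individuals
#'
#' @param object A [wtraj_fit] object.
#' @param newdata A [participant_record] or list of them.
#' @param method One of the trained methods.
#' @param ... Unused.
#' @return Data frame with one row per individual: `id`, `frame` (months),
#'   `eligible`, `reason`, `three_class`, `five_class` (`NA` for frames of
#'   at most 4 months), and `dist_<class>` columns with the DTW distances to
#'   the five cluster means. Ineligible individuals are flagged, not
#'   dropped.
#' @export
predict.wtraj_fit <- function(object, newdata, method = "logistic_regression",
                              ...) {
  if (inherits(newdata, "participant_record")) newdata <- list(newdata)
  rows <- lapply(newdata, function(rec) {
    base <- data.frame(id = rec$id, frame = NA_character_, eligible = FALSE,
                       reason = NA_character_, three_class = NA_character_,
                       five_class = NA_character_, stringsAsFactors = FALSE)
    dist_cols <- as.list(setNames(rep(NA_real_, 5),
                                  paste0("dist_", FIVE_CLASSES)))
    res <- tryCatch(predict_individual(rec, object, method),
                    error = function(e) e)
    if (inherits(res, "error")) {
      base$reason <- conditionMessage(res)
    } else {
      base$frame <- res$frame$label
      base$eligible <- TRUE
      base$three_class <- res$three_class
      base$five_class <- res$five_class
      dist_cols <- as.list(setNames(unname(res$dtw_distances),
                                    paste0("dist_", FIVE_CLASSES)))
    }
    cbind(base, as.data.frame(dist_cols))
  })
  do.call(rbind, rows)
}
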