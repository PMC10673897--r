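# A tiny fitted framework reused across the blocks in this file.
sim_small <- generate_cohort(sim_config(n_per_class = rep(10L, 5),
                                        noise_sd = 0.4, seed = 41))
model_small <- derive_cluster_model(sim_small$cohort)
fit_small <- wtraj_fit(sim_small$cohort,
                       methods = c("logistic_regression", "linear_regression"),
                       cluster_model = model_small,
                       control = wtraj_control(seed = 6))

test_that("feature encodings have the specified lengths and content", {
  rec <- make_record(c(0, 270), c(100, 100), height = 200)  # flat, BMI 25
  s <- percent_change_series(rec)
  f2m <- time_frame(2)
  f1 <- build_features(restrict_to_frame(s, f2m), rec, f2m, "bmi_last")
  expect_equal(unname(f1), c(25, 0))
  # grid ends <= 60 are {15, 30, 60}: BMI + 3 history values
  f2 <- build_features(restrict_to_frame(s, f2m), rec, f2m, "bmi_history")
  expect_length(f2, 4)
  expect_equal(unname(f2), c(25, 0, 0, 0))
  f4 <- build_features(restrict_to_frame(s, f2m), rec, f2m, "daily")
  expect_length(f4, 1 + 60)
  # a series equal to a cluster mean has zero DTW distance at its position
  fr8 <- time_frame(8)
  mean_series <- daily_series(model_small$means[1:241, "low_gain"], 240, 100)
  f3 <- build_features(mean_series, rec, fr8, "dtw_dists", model_small)
  expect_length(f3, 5)
  expect_equal(unname(f3["low_gain"]), 0)
  expect_true(all(f3[names(f3) != "low_gain"] > 0))
  expect_error(build_features(s, rec, f2m, "bmi_last"), "restricted")
  expect_error(build_features(restrict_to_frame(s, f2m), rec, f2m, "pca"),
               "unknown encoding")
})

test_that("stratified folds deal classes evenly with round-robin remainders", {
  labels <- rep(c("a", "b", "c", "d", "e"), each = 20)
  f <- stratified_folds(labels, 5, seed = 2)
  tab <- table(labels, f)
  expect_true(all(tab == 4))
  # class of 7 across 5 folds: sizes 2,2,1,1,1 starting at the first fold
  f2 <- stratified_folds(c(rep("a", 7), rep("b", 10)), 5, seed = 2)
  expect_equal(as.vector(table(f2[1:7])), c(2, 2, 1, 1, 1))
  expect_identical(stratified_folds(labels, 5, seed = 9),
                   stratified_folds(labels, 5, seed = 9))
  expect_error(stratified_folds(c("a", rep("b", 9)), 5, seed = 1),
               "stratification")
})

test_that("regression predictions convert to classes with lower-class boundaries", {
  s5 <- class_scheme("five_class")
  cuts <- default_cutoffs(s5)
  expect_equal(regression_to_class(-12, cuts, s5), "high_loss")
  expect_equal(regression_to_class(-2.4, cuts, s5), "moderate_loss")
  expect_equal(regression_to_class(5, cuts, s5), "high_gain")
  expect_equal(regression_to_class(c(-9.2, -9.19), cuts, s5),
               c("high_loss", "moderate_loss"))
  s3 <- class_scheme("three_class")
  expect_equal(regression_to_class(0.4, default_cutoffs(s3), s3), "gain")
})

test_that("frame selection picks the nearest frame, ties to the larger", {
  expect_equal(select_frame(105)$months, 4)   # 3.5 months of data
  expect_equal(select_frame(15)$months, 0.5)
  expect_equal(select_frame(250)$months, 8)
  expect_equal(select_frame(45)$months, 2)    # tie 30 vs 60 -> larger
  expect_equal(select_frame(1)$months, 0.5)
})

test_that("eligibility needs two in-frame entries and a recent last entry", {
  r <- make_record(c(0, 10), c(100, 99))
  expect_true(check_eligibility(r, time_frame(0.5))$eligible)
  e <- check_eligibility(r, time_frame(3))
  expect_false(e$eligible)   # last entry 10 < 90 - 30
  expect_match(e$reasons, "30 days")
  single <- make_record(0, 100)
  e2 <- check_eligibility(single, time_frame(0.5))
  expect_false(e2$eligible)
  expect_match(e2$reasons[1], "fewer than two")
})

test_that("training is deterministic and separable cohorts are learned exactly", {
  lin <- linear_cohort(n_per_class = 8L, seed = 2)
  fit1 <- wtraj_fit(lin$cohort,
                    methods = c("logistic_regression", "linear_regression"),
                    schemes = "three_class", control = wtraj_control(seed = 5))
  cv <- fit1$cv_accuracy
  # separable by construction: logistic CV accuracy 1 at the 8-month frame
  expect_equal(cv$cv_accuracy[cv$method == "logistic_regression" &
                                cv$frame == "8"], 1)
  # regression route: optimized cutoffs classify the training data exactly
  pred <- vapply(lin$cohort, function(r)
    as.character(predict_at_frame(r, fit1, time_frame(8),
                                  method = "linear_regression")), character(1))
  expect_equal(pred, unname(fit1$labels$three_class))
  fit2 <- wtraj_fit(lin$cohort,
                    methods = c("logistic_regression", "linear_regression"),
                    schemes = "three_class", control = wtraj_control(seed = 5))
  expect_identical(fit1$cv_accuracy, fit2$cv_accuracy)
  # cluster labels equal generator truth on this separable cohort
  expect_equal(unname(fit1$labels$five_class_truth), unname(lin$truth))
})

test_that("longer follow-up does not hurt logistic-regression CV accuracy", {
  cv <- fit_small$cv_accuracy
  l3 <- cv[cv$method == "logistic_regression" & cv$scheme == "three_class", ]
  expect_gte(l3$cv_accuracy[l3$frame == "8"], l3$cv_accuracy[l3$frame == "0.5"])
})

test_that("prediction reports five-class results only beyond 4 months", {
  arche <- archetype_specs()
  curve <- arche[[1]]$curve   # high-loss archetype
  days <- seq(0, 240, by = 10)
  rec_long <- make_record(days, 100 * (1 + curve(days) / 100), id = "long")
  p <- predict_individual(rec_long, fit_small)
  expect_equal(p$frame$months, 8)
  expect_equal(p$three_class, "loss")
  expect_equal(p$five_class, "high_loss")
  expect_equal(names(which.min(p$dtw_distances)), "high_loss")
  expect_s3_class(p, "wtraj_prediction")

  days2 <- seq(0, 60, by = 6)
  rec_short <- make_record(days2, 100 * (1 + curve(days2) / 100), id = "short")
  p2 <- predict_individual(rec_short, fit_small)
  expect_equal(p2$frame$months, 2)
  expect_true(is.na(p2$five_class))
  expect_false(is.na(p2$three_class))

  # last in-frame entry too old for the selected 8-month frame
  expect_error(predict_individual(make_record(c(0, 150, 270),
                                              c(100, 97, 95)),
                                  fit_small), "not eligible")
})

test_that("the predict method flags ineligible individuals instead of failing", {
  recs <- list(make_record(c(0, 100, 240), c(100, 95, 90), id = "ok"),
               make_record(c(0, 150, 270), c(100, 97, 95), id = "stale"))
  out <- predict(fit_small, recs)
  expect_equal(nrow(out), 2)
  expect_true(out$eligible[1])
  expect_false(out$eligible[2])
  expect_match(out$reason[2], "not eligible")
  expect_identical(out, predict(fit_small, recs))
})

test_that("fixed-frame prediction honours eligibility and schemes", {
  rec <- make_record(seq(0, 120, by = 10), seq(100, 94, length.out = 13),
                     id = "v1")
  lab3 <- predict_at_frame(rec, fit_small, time_frame(4))
  expect_true(lab3 %in% class_scheme("three_class")$classes)
  lab5 <- predict_at_frame(rec, fit_small, time_frame(4),
                           scheme = "five_class")
  expect_true(lab5 %in% class_scheme("five_class")$classes)
  too_far <- predict_at_frame(rec, fit_small, time_frame(8))
  expect_true(is.na(too_far))
  expect_match(attr(too_far, "reasons"), "30 days")
})
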