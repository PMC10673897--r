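test_that("generation is deterministic and respects configured ranges", {
  cfg <- sim_config(n_per_class = rep(5L, 5), seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_length(a$cohort, 25)
  expect_equal(unname(table(a$truth)), rep(5L, 5), ignore_attr = TRUE)
  for (r in a$cohort) {
    n <- nrow(r$entries)
    expect_gte(n, cfg$entry_count_range[1])
    expect_lte(n, cfg$entry_count_range[2])
    expect_gte(r$height_cm, cfg$height_range[1])
    expect_lte(r$height_cm, cfg$height_range[2])
    expect_equal(r$entries$day[1], 0L)
    expect_equal(max(r$entries$day), 270L)
    w0 <- r$entries$weight[1]   # day-0 weight is the baseline draw itself
    expect_gte(w0, cfg$baseline_weight_range[1])
    expect_lte(w0, cfg$baseline_weight_range[2])
  }
  c2 <- generate_cohort(sim_config(n_per_class = rep(5L, 5), seed = 78))
  expect_false(identical(a$cohort, c2$cohort))
})

test_that("default cohorts never violate the daily-change screen; stress mode can", {
  sim <- generate_cohort(sim_config(n_per_class = rep(8L, 5), noise_sd = 1.5,
                                    seed = 19))
  res <- apply_exclusions(sim$cohort,
                          exclusion_config(min_entries = NULL,
                                           min_span_days = NULL,
                                           min_height_cm = NULL,
                                           exclude_medication = FALSE))
  expect_length(res$kept, length(sim$cohort))
  stress <- generate_cohort(sim_config(n_per_class = rep(8L, 5),
                                       noise_sd = 4, stress = TRUE, seed = 19))
  res2 <- apply_exclusions(stress$cohort,
                           exclusion_config(min_entries = NULL,
                                            min_span_days = NULL,
                                            min_height_cm = NULL,
                                            exclude_medication = FALSE))
  expect_gt(nrow(res2$log), 0)
})

test_that("noiseless dense sampling inverts the generative curve exactly", {
  cfg <- sim_config(n_per_class = rep(1L, 5), noise_sd = 0,
                    entry_count_mean = 271, entry_count_sd = 0,
                    entry_count_range = c(271L, 271L), seed = 23)
  sim <- generate_cohort(cfg)
  arche <- archetype_specs()
  for (i in seq_along(sim$cohort)) {
    s <- percent_change_series(sim$cohort[[i]])
    cl <- sim$truth[[sim$cohort[[i]]$id]]
    spec <- arche[[match(cl, vapply(arche, `[[`, character(1), "name"))]]
    expect_equal(s$values, spec$curve(0:270), tolerance = 1e-9)
  }
})

test_that("pipeline truth equals generator truth at zero noise, and recovery degrades with noise", {
  dense <- sim_config(n_per_class = rep(6L, 5), noise_sd = 0,
                      entry_count_mean = 271, entry_count_sd = 0,
                      entry_count_range = c(271L, 271L), seed = 29)
  sim <- generate_cohort(dense)
  model <- derive_cluster_model(sim$cohort)
  labs <- vapply(sim$cohort, function(r)
    as.character(assign_class_by_dtw(
      extrapolate_to(percent_change_series(r), 270L), model)), character(1))
  expect_equal(labs, unname(sim$truth))

  recovery <- vapply(c(0, 1, 4), function(ns) {
    s <- generate_cohort(sim_config(n_per_class = rep(6L, 5), noise_sd = ns,
                                    seed = 53))
    l <- vapply(s$cohort, function(r)
      as.character(assign_class_by_dtw(
        extrapolate_to(percent_change_series(r), 270L), model)), character(1))
    mean(l == unname(s$truth))
  }, numeric(1))
  expect_true(all(diff(recovery) <= 0))
  expect_equal(recovery[1], 1)
})

test_that("noisy archetype draws are almost always assigned to their archetype", {
  sim <- generate_cohort(sim_config(n_per_class = rep(40L, 5), noise_sd = 0.5,
                                    seed = 61))
  arche <- archetype_specs()
  init <- t(vapply(arche, function(a) a$curve(0:270), numeric(271)))
  model <- cluster_model(t(init), default_cutoffs(class_scheme("five_class")),
                         default_cutoffs(class_scheme("three_class")))
  labs <- vapply(sim$cohort, function(r)
    as.character(assign_class_by_dtw(
      extrapolate_to(percent_change_series(r), 270L), model)), character(1))
  expect_gte(mean(labs == unname(sim$truth)), 0.95)
})

test_that("class prevalence is an empirical probability vector", {
  expect_equal(class_prevalence(c("a", "a", "b", "b")), c(a = 0.5, b = 0.5))
  expect_equal(class_prevalence("x"), c(x = 1))
  withr::with_seed(2, truth <- sample(c("u", "v", "w"), 50, replace = TRUE))
  p <- class_prevalence(truth)
  expect_equal(sum(p), 1)
  expect_equal(unname(p["u"]), sum(truth == "u") / 50)
})
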