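test_that("consensus bookkeeping excludes label-flipping individuals", {
  V <- rbind(matrix(0, 3, 10), matrix(5, 3, 10))
  V[6, ] <- 4.0   # still nearest cluster 2, but variant 2 disagrees
  ref <- c(1L, 1L, 1L, 2L, 2L, 2L)
  other <- c(2L, 2L, 2L, 1L, 1L, 2L)  # permuted labels; individual 6 flips
  res <- wtraj:::consensus_core(list(ref, other), V, k = 2L)
  expect_equal(res$consensus_fraction, 5 / 6)
  expect_equal(res$consensual, c(rep(TRUE, 5), FALSE))
  expect_equal(res$centroids[1, ], rep(0, 10))
  expect_equal(res$centroids[2, ], rep(5, 10))   # row 6 excluded from the mean
  # all variants identical -> full agreement and plain per-cluster means
  res2 <- wtraj:::consensus_core(list(ref, ref, ref), V, k = 2L)
  expect_equal(res2$consensus_fraction, 1)
  expect_equal(res2$centroids[2, ], colMeans(V[4:6, ]))
  # a cluster with no consensual member is degenerate
  expect_error(
    wtraj:::consensus_core(list(c(1L, 1L, 2L), c(2L, 2L, 2L)),
                           matrix(rnorm(30), 3), k = 2L),
    "degenerate")
})

test_that("consensus centroids recover well-separated archetype means", {
  sim <- generate_cohort(sim_config(n_per_class = rep(10L, 5), noise_sd = 0.3,
                                    seed = 21))
  series <- lapply(sim$cohort, function(r)
    extrapolate_to(percent_change_series(r), 270L))
  res <- consensus_initial_centroids(series, k = 5)
  expect_gte(res$consensus_fraction, 0.9)
  arche <- archetype_specs()
  true_means <- t(vapply(arche, function(a) a$curve(0:270), numeric(271)))
  ord <- order(res$centroids[, 271])
  for (i in 1:5)
    expect_lt(max(abs(res$centroids[ord[i], ] - true_means[i, ])), 1)
})

test_that("DTW k-means converges immediately on its own centroids and refines noise", {
  centroids <- rbind(seq(0, -10, length.out = 50), seq(0, 4, length.out = 50))
  series <- list(centroids[1, ], centroids[2, ], centroids[1, ], centroids[2, ])
  km <- dtw_kmeans(series, centroids)
  expect_equal(km$assignments, c(1L, 2L, 1L, 2L))
  expect_equal(km$objective[1], 0)
  expect_lte(km$iterations, 2)
  expect_equal(km$means, centroids)

  # noiseless archetype cohort with archetype means as init: labels recovered
  sim <- generate_cohort(sim_config(n_per_class = rep(6L, 5), noise_sd = 0,
                                    seed = 3))
  series <- lapply(sim$cohort, function(r)
    extrapolate_to(percent_change_series(r), 270L))
  init <- t(vapply(archetype_specs(), function(a) a$curve(0:270), numeric(271)))
  km2 <- dtw_kmeans(series, init)
  truth_idx <- match(sim$truth, c("high_loss", "moderate_loss",
                                  "insufficient_loss", "low_gain", "high_gain"))
  expect_equal(km2$assignments, unname(truth_idx))
})

test_that("the k-means objective is non-increasing and a fixed point is stable", {
  withr::with_seed(17, {
    series <- lapply(1:30, function(i) cumsum(rnorm(40, sd = 0.5)))
    init <- do.call(rbind, series[sample(30, 4)])
  })
  km <- dtw_kmeans(series, init)
  expect_true(all(diff(km$objective) <= 1e-9))
  again <- dtw_kmeans(series, km$means)
  expect_equal(again$means, km$means)
  expect_equal(again$assignments, km$assignments)
})

test_that("nearest-cluster assignment truncates means and breaks ties low", {
  sim <- generate_cohort(sim_config(n_per_class = rep(8L, 5), noise_sd = 0.4,
                                    seed = 31))
  model <- derive_cluster_model(sim$cohort)
  # a series equal to a cluster mean is assigned to it with distance 0
  lab <- assign_class_by_dtw(model$means[, "insufficient_loss"], model)
  expect_equal(as.character(lab), "insufficient_loss")
  expect_equal(unname(attr(lab, "distances")["insufficient_loss"]), 0)
  # frame-limited assignment compares against truncated means
  short <- model$means[1:61, "high_loss"]
  lab2 <- assign_class_by_dtw(short, model, frame_end = 60)
  expect_equal(as.character(lab2), "high_loss")
  # exact midpoint between the first two means -> tie -> lower class index
  mid <- (model$means[, 1] + model$means[, 2]) / 2
  d <- attr(assign_class_by_dtw(mid, model), "distances")
  if (abs(d[1] - d[2]) < 1e-9)
    expect_equal(as.character(assign_class_by_dtw(mid, model)), "high_loss")
})

test_that("five-to-three class collapse merges losses and gains", {
  s3 <- class_scheme("three_class")
  expect_equal(collapse_classes("high_loss", s3), "loss")
  expect_equal(collapse_classes("moderate_loss", s3), "loss")
  expect_equal(collapse_classes("insufficient_loss", s3), "insufficient_loss")
  expect_equal(collapse_classes(c("low_gain", "high_gain"), s3),
               c("gain", "gain"))
  expect_error(collapse_classes("big_loss", s3), "unknown")
  s5 <- class_scheme("five_class")
  expect_equal(collapse_classes("low_gain", s5), "low_gain")
})

test_that("cutoff optimization matches the stated examples", {
  cuts <- optimize_cutoffs(c(-10, -5, -1, 2),
                           c("loss", "loss", "gain", "gain"),
                           c("loss", "gain"))
  expect_equal(cuts, -5)
  # perfectly separated classes give zero training errors at the cutoffs
  x <- c(-12, -11, -7, -6, -1, 0, 1.4, 1.6, 5, 6)
  l <- rep(c("high_loss", "moderate_loss", "insufficient_loss",
             "low_gain", "high_gain"), each = 2)
  cuts5 <- optimize_cutoffs(x, l, class_scheme("five_class"))
  pred <- regression_to_class(x, cuts5, class_scheme("five_class"))
  expect_equal(pred, l)
  # tie at one error resolves to the largest candidate value
  xt <- c(-4, -3, -2, -1, 0, 1)
  lt <- c("loss", "gain", "loss", "gain", "gain", "gain")
  expect_equal(optimize_cutoffs(xt, lt, c("loss", "gain")),
               cutoffs_oracle(xt, lt, c("loss", "gain")))
  expect_error(optimize_cutoffs(1:3, rep("loss", 3), c("loss", "gain")),
               "no members")
})

test_that("cutoff optimization agrees with brute force on random instances", {
  withr::with_seed(8, {
    for (i in 1:30) {
      k <- sample(2:5, 1)
      classes <- paste0("c", seq_len(k))
      n <- sample(k:40, 1)
      labels <- c(classes, sample(classes, max(0, n - k), replace = TRUE))
      # class-ordered means with noise so ties and overlap both occur
      x <- round(rnorm(length(labels), mean = 3 * match(labels, classes)), 1)
      expect_equal(optimize_cutoffs(x, labels, classes),
                   cutoffs_oracle(x, labels, classes))
    }
  })
})

test_that("cluster model JSON round-trips", {
  sim <- generate_cohort(sim_config(n_per_class = rep(6L, 5), noise_sd = 0.3,
                                    seed = 13))
  model <- derive_cluster_model(sim$cohort)
  path <- tempfile(fileext = ".json")
  write_cluster_model(model, path)
  back <- read_cluster_model(path)
  expect_equal(back$means, model$means)
  expect_equal(back$five_class_cutoffs, model$five_class_cutoffs)
  expect_equal(back$three_class_cutoffs, model$three_class_cutoffs)
  expect_equal(back$dtw_cfg$local_cost, model$dtw_cfg$local_cost)
})
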