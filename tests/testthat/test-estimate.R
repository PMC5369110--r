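test_that("locational features follow their geometric definitions", {
  env <- list(
    greenspace = tibble::tibble(x = 30, y = 40),
    waterbody = tibble::tibble(x = c(0, 100), y = c(10, 0)),
    busstop = tibble::tibble(x = c(50, 100, 101, 500), y = 0),
    city_centre = c(0, 0)
  )
  nodes <- tibble::tibble(id = "n1", x = 0, y = 0, count_total = 7L)
  f <- build_features(nodes, env)
  expect_equal(f$Dis_to_Citycentre, 0)            # node at the centre
  expect_equal(f$Dis_to_Greenspace, 50)           # 3-4-5 triangle
  expect_equal(f$Dis_to_Waterbody, 10)
  expect_equal(f$Num_nearest_busstops, 2L)        # 100 m is inclusive, 101 is not
  expect_equal(f$Num_cycling, 7)
})

test_that("correlation screening flags weak linear association", {
  set.seed(17)
  n <- 10000
  target <- rnorm(n)
  feats <- tibble::tibble(same = target, neg = -target,
                          noise = runif(n), flat = rep(1, n))
  scr <- screen_correlations(feats, target)
  expect_equal(scr$r[scr$feature == "same"], 1)
  expect_equal(scr$r[scr$feature == "neg"], -1)
  expect_lt(abs(scr$r[scr$feature == "noise"]), 0.05)
  expect_true(is.na(scr$r[scr$feature == "flat"]))
  expect_equal(scr$linearly_correlated, c(TRUE, TRUE, FALSE, FALSE))
})

test_that("k-fold split is balanced, exhaustive and seeded", {
  f10 <- kfold_split(10, 10, seed = 1L)
  expect_equal(sort(unique(f10)), 1:10)
  expect_true(all(table(f10) == 1))
  f23 <- kfold_split(23, 10, seed = 1L)
  sizes <- sort(as.integer(table(f23)))
  expect_equal(sizes, c(rep(2L, 7), rep(3L, 3)))
  expect_identical(kfold_split(23, 10, seed = 4L), kfold_split(23, 10, seed = 4L))
  expect_false(identical(kfold_split(23, 10, seed = 4L), kfold_split(23, 10, seed = 5L)))
  expect_error(kfold_split(5, 6), "exceed")
  expect_error(kfold_split(5, 1), "at least 2")
})

test_that("models interpolate linear truths, handle constants, and are seeded", {
  set.seed(3)
  X <- tibble::tibble(a = runif(60), b = runif(60))
  y <- 2 + 3 * X$a - 5 * X$b
  Xte <- tibble::tibble(a = runif(20), b = runif(20))
  yte <- 2 + 3 * Xte$a - 5 * Xte$b
  pred <- fit_and_predict("OLS", X, y, Xte)
  expect_equal(pred, yte, tolerance = 1e-8)
  for (m in c("OLS", "MLP", "SVM", "RF")) {
    expect_equal(fit_and_predict(m, X, rep(4.2, 60), Xte, seed = 1L),
                 rep(4.2, 20), tolerance = 1e-6)
  }
  yr <- y + rnorm(60, 0, 0.3)
  expect_identical(fit_and_predict("RF", X, yr, Xte, seed = 7L),
                   fit_and_predict("RF", X, yr, Xte, seed = 7L))
  expect_identical(fit_and_predict("MLP", X, yr, Xte, seed = 7L),
                   fit_and_predict("MLP", X, yr, Xte, seed = 7L))
  expect_error(fit_and_predict("GBM", X, y, Xte), "unknown model_kind")
  expect_error(fit_and_predict("OLS", X[1:2, ], y[1:2], Xte), "degenerate")
})

test_that("cross-validation pools each row exactly once and r is affine-invariant", {
  set.seed(23)
  n <- 200
  feats <- tibble::tibble(id = as.character(1:n), a = runif(n), b = runif(n))
  target <- 1 + 2 * feats$a + rnorm(n, 0, 0.1)
  cv <- cross_validated_correlation(feats, target, "OLS", k = 5, seed = 2L)
  expect_equal(sort(cv$predictions$id), sort(feats$id))
  expect_equal(anyDuplicated(cv$predictions$id), 0L)
  expect_equal(sort(unique(cv$predictions$fold)), 1:5)
  # Pearson r unchanged by positive affine rescaling of predictions
  p <- cv$predictions
  expect_equal(cor(10 + 3 * p$predicted, p$actual), cv$result$pearson_r)
  expect_gt(cv$result$pearson_r, 0.95)
  # deterministic planted linear truth: OLS recovers it essentially exactly
  exact <- 1 + 2 * feats$a - feats$b
  cv2 <- cross_validated_correlation(feats, exact, "OLS", k = 5, seed = 2L)
  expect_gte(cv2$result$pearson_r, 0.999)
})

test_that("tidy/glance views expose per-model and best-model summaries", {
  set.seed(29)
  n <- 120
  feats <- tibble::tibble(a = runif(n), b = runif(n))
  target <- 3 * feats$a + rnorm(n, 0, 0.2)
  est <- estimate_purpose(feats, target, models = c("OLS", "RF"), k = 4, seed = 1L)
  td <- tidy(est)
  expect_equal(td$model, c("OLS", "RF"))
  expect_true(all(td$pearson_r >= -1 & td$pearson_r <= 1))
  gl <- glance(est)
  expect_equal(gl$best_model, td$model[which.max(td$pearson_r)])
  expect_equal(gl$n, n)
})
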