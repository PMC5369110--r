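test_that("weighted exposure means match hand evaluation and stay within bounds", {
  nodes <- tibble::tibble(count_noncommute = c(2L, 1L), count_commute = c(0L, 3L),
                          pm10 = c(10, 16))
  expect_equal(weighted_exposure_mean(nodes, "noncommute", "pm10"), 12)
  expect_equal(weighted_exposure_mean(nodes, "commute", "pm10"), 16)
  # constant field: mean = the constant for both purposes
  const <- tibble::tibble(count_noncommute = c(4L, 1L), count_commute = c(2L, 2L),
                          pm10 = c(7.5, 7.5))
  expect_equal(weighted_exposure_mean(const, "noncommute", "pm10"), 7.5)
  expect_equal(weighted_exposure_mean(const, "commute", "pm10"), 7.5)
  # bounds property on random fixtures
  set.seed(61)
  for (rep in 1:10) {
    df <- tibble::tibble(count_noncommute = rpois(20, 3), count_commute = rpois(20, 3),
                         pm10 = runif(20, 5, 20))
    if (sum(df$count_noncommute) == 0) next
    m <- weighted_exposure_mean(df, "noncommute", "pm10")
    expect_gte(m, min(df$pm10)); expect_lte(m, max(df$pm10))
  }
  zero <- tibble::tibble(count_noncommute = 0L, count_commute = 1L, pm10 = 5)
  expect_error(weighted_exposure_mean(zero, "noncommute", "pm10"), "undefined")
})

test_that("high-exposure percentage uses a strict guideline threshold", {
  nodes <- tibble::tibble(count_noncommute = c(2L, 2L), count_commute = c(0L, 0L),
                          pm25 = c(11, 9))
  expect_equal(high_exposure_percentage(nodes, "noncommute", 10), 0.5)
  # all cells at or below the guideline -> 0 (exactly 10 is NOT high)
  at <- tibble::tibble(count_noncommute = c(1L, 1L), count_commute = 0L,
                       pm25 = c(10, 8))
  expect_equal(high_exposure_percentage(at, "noncommute", 10), 0)
  expect_equal(high_exposure_percentage(nodes, "noncommute", Inf), 0)
  # nodewise computation equals the expanded-activity fraction
  set.seed(8)
  df <- tibble::tibble(count_noncommute = rpois(30, 2) + 1L, count_commute = 0L,
                       pm25 = runif(30, 8, 12))
  expanded <- rep(df$pm25, df$count_noncommute)
  expect_equal(high_exposure_percentage(df, "noncommute", 10),
               mean(expanded > 10))
})

test_that("band crosstab counts areas into half-open bands summing to 100%", {
  areas <- tibble::tibble(area_id = sprintf("a%d", 1:4),
                          cluster_type = "high",
                          pm10 = c(11, 13, 13, 15))
  tab <- band_crosstab(areas, "pm10", c(0, 10, 12, 14, Inf))
  expect_equal(tab$high, c(0, 25, 50, 25))
  expect_equal(sum(tab$high), 100)
  mixed <- tibble::tibble(area_id = sprintf("a%d", 1:6),
                          cluster_type = rep(c("high", "low", "outside"), 2),
                          pm10 = c(5, 5, 5, 5, 5, 5))
  tab2 <- band_crosstab(mixed, "pm10", c(0, 10, Inf))
  expect_equal(unname(unlist(tab2[1, c("high", "outside", "low")])), c(100, 100, 100))
  expect_error(band_crosstab(areas, "pm10", c(0, 10, 12)), "outside the configured")
  expect_error(band_crosstab(areas, "pm10", c(0, 0, 12)), "strictly increasing")
})

test_that("weighted rank-sum test equals the expanded-sample Wilcoxon", {
  # symmetric identical weighted samples: statistic at its null mean, p ~ 1
  sym <- weighted_rank_sum_test(c(1, 2, 3), c(2L, 2L, 2L), c(2L, 2L, 2L),
                                "two.sided", exact = FALSE)
  expect_equal(sym$statistic, 6 * 6 / 2)
  expect_gt(sym$p_value, 0.9)
  # classical exact example: {1,2,3} vs {4,5,6}, p = 1/20
  ex <- weighted_rank_sum_test(1:6, c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1), "less")
  expect_equal(ex$p_value, 0.05)
  expect_equal(ex$method, "exact enumeration")
  expect_equal(ex$p_value,
               wilcox.test(1:3, 4:6, alternative = "less", exact = TRUE)$p.value)
  # oracle equivalence on random weighted fixtures (normal approximation path)
  set.seed(40)
  for (rep in 1:15) {
    v <- sort(sample(seq(5, 20, by = 0.5), 8))
    w1 <- rpois(8, 4); w2 <- rpois(8, 4)
    if (sum(w1) == 0 || sum(w2) == 0) next
    for (alt in c("less", "greater", "two.sided")) {
      mine <- weighted_rank_sum_test(v, w1, w2, alt, exact = FALSE)
      oracle <- wilcox.test(rep(v, w1), rep(v, w2), alternative = alt,
                            exact = FALSE, correct = TRUE)
      expect_equal(mine$statistic, unname(oracle$statistic))
      expect_equal(mine$p_value, oracle$p.value, tolerance = 1e-12)
    }
  }
  expect_error(weighted_rank_sum_test(1:3, c(0, 0, 0), c(1, 1, 1)), "positive total")
})

test_that("rank-sum p is invariant to positive rescaling; means are equivariant", {
  set.seed(55)
  v <- runif(10, 8, 15); w1 <- rpois(10, 3) + 1L; w2 <- rpois(10, 3) + 1L
  base <- weighted_rank_sum_test(v, w1, w2, "less", exact = FALSE)
  scaled <- weighted_rank_sum_test(3.7 * v, w1, w2, "less", exact = FALSE)
  expect_equal(base$p_value, scaled$p_value)
  df <- tibble::tibble(count_noncommute = w1, count_commute = w2, pm10 = v)
  df2 <- dplyr::mutate(df, pm10 = pm10 * 3.7)
  expect_equal(weighted_exposure_mean(df2, "noncommute", "pm10"),
               3.7 * weighted_exposure_mean(df, "noncommute", "pm10"))
})

test_that("exposure report is flat under uniform share and uniform PM", {
  cfg <- small_sim_config(seed = 13L, planted_regions = list(),
                          pm10_amplitude = 0, pm_noise_sd = 0,
                          noise_node_fraction = 0)
  b <- generate_study(cfg)
  rep <- exposure_report(b)
  s <- rep$summary
  expect_lt(abs(s$mean_pm10_non - s$mean_pm10_com), 1e-12)
  expect_lt(abs(s$mean_pm25_non - s$mean_pm25_com), 1e-12)
  expect_equal(s$wilcoxon_p_pm10, 1)
  expect_equal(s$wilcoxon_p_pm10_two_sided, 1)
})
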