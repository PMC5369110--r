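test_that("identical config and seed reproduce identical bundles", {
  b1 <- generate_study(small_sim_config(seed = 3L))
  b2 <- generate_study(small_sim_config(seed = 3L))
  expect_identical(b1$nodes, b2$nodes)
  expect_identical(b1$pm_cells, b2$pm_cells)
  expect_identical(b1$env_layers, b2$env_layers)
  expect_identical(b1$truth, b2$truth)
  b3 <- generate_study(small_sim_config(seed = 4L))
  expect_false(identical(b1$nodes, b3$nodes))
})

test_that("clean generation satisfies count invariants everywhere", {
  b <- generate_study(small_sim_config(seed = 2L, noise_node_fraction = 0))
  expect_true(all(b$nodes$count_total >= 1))
  expect_true(all(b$nodes$count_commute <= b$nodes$count_total))
  expect_true(all(b$nodes$count_commute >= 0))
  # conservation after inference
  nd <- infer_noncommute(b$nodes)
  expect_equal(nd$count_commute + nd$count_noncommute, nd$count_total)
})

test_that("planted commute-share override drives area-level rates (Monte-Carlo)", {
  # planted share 0.2 vs uniform background 0.6 -> non-commuting rates
  # near 0.8 inside and 0.4 outside
  b <- generate_study(sim_config(seed = 6L, noise_node_fraction = 0))
  expect_gt(sum(b$nodes$count_total), 1e4)
  nodes <- infer_noncommute(b$nodes)
  rates <- noncommuting_rate(aggregate_to_areas(nodes, b$node_area, b$areas$id))
  planted <- rates$area_id %in% b$truth$planted_area_ids
  expect_equal(mean(rates$rate_non_act[planted], na.rm = TRUE), 0.8, tolerance = 0.05 / 0.8)
  expect_equal(mean(rates$rate_non_act[!planted], na.rm = TRUE), 0.4, tolerance = 0.05 / 0.4)
})

test_that("PM surface follows its closed form and decays from the centre", {
  cells <- make_pm_grid(c(0, 4000, 0, 4000), 1000)
  pars <- list(pm10_base = 10, pm10_amplitude = 5, pm10_decay_scale = 2000,
               pm25_ratio = 0.7, pm_noise_sd = 0)
  centre <- c(2000, 2000)
  surf <- make_pm_surface(cells, centre, pars, seed = 1L)
  d <- sqrt((surf$centre_x - centre[1])^2 + (surf$centre_y - centre[2])^2)
  expect_equal(surf$pm10, 10 + 5 * exp(-d / 2000))
  expect_equal(surf$pm25, 0.7 * surf$pm10)
  # closed form at d = 0 and the base far limit
  expect_equal(10 + 5 * exp(0), 15)
  ord <- order(d)
  expect_true(all(diff(surf$pm10[ord]) <= 1e-12))
  # flat surface when amplitude = 0
  flat <- make_pm_surface(cells, centre,
                          modifyList(pars, list(pm10_amplitude = 0)), seed = 1L)
  expect_true(all(flat$pm10 == 10))
})

test_that("activity totals have a straight-line CCDF on the log-linear scale", {
  cfg <- sim_config(seed = 8L, n_nodes = 10000L, noise_node_fraction = 0)
  b <- generate_study(cfg)
  cc <- ccdf(b$nodes$count_total)
  # fit over the well-estimated part of the tail (at least 10 exceedances)
  cc <- cc[cc$p >= 10 / nrow(b$nodes), ]
  fit <- stats::lm(log(p) ~ x, data = cc)
  expect_gte(summary(fit)$r.squared, 0.99)
  # fitted tail rate recovers the configured rate
  expect_equal(-unname(coef(fit)[2]), cfg$count_tail_rate, tolerance = 0.1)
})

test_that("degenerate commute shares yield all-commute or no-commute nodes", {
  all_com <- generate_study(small_sim_config(
    seed = 2L, commute_share_centre = 1, commute_share_edge = 1,
    planted_regions = list(), noise_node_fraction = 0))
  expect_true(all(all_com$nodes$count_commute == all_com$nodes$count_total))
  none <- generate_study(small_sim_config(
    seed = 2L, commute_share_centre = 0, commute_share_edge = 0,
    planted_regions = list(), noise_node_fraction = 0))
  expect_true(all(none$nodes$count_commute == 0L))
})

test_that("noise injection corrupts the floor-count and cleaning recovers the clean set", {
  b <- generate_study(small_sim_config(seed = 5L, noise_node_fraction = 0))
  res <- inject_noise_nodes(b$nodes, 0.1, seed = 77L)
  expect_equal(length(res$corrupted_ids), floor(0.1 * nrow(b$nodes)))
  cleaned <- clean_nodes(res$nodes)
  expect_setequal(cleaned$removed$id, res$corrupted_ids)
  expect_setequal(cleaned$kept$id, setdiff(b$nodes$id, res$corrupted_ids))
  # fraction 0 is a no-op
  noop <- inject_noise_nodes(b$nodes, 0, seed = 77L)
  expect_identical(noop$nodes, b$nodes)
  expect_length(noop$corrupted_ids, 0L)
})

test_that("environment layers are seeded and bus-stop density matches the Poisson intensity", {
  ext <- c(0, 10000, 0, 10000)
  counts <- c(greenspace = 5, waterbody = 5, busstop = 1000)
  e1 <- make_env_layers(ext, counts, seed = 12L)
  e2 <- make_env_layers(ext, counts, seed = 12L)
  expect_identical(e1, e2)
  expect_equal(e1$city_centre, c(5000, 5000))
  # expected bus stops within 100 m of a random node:
  # 1000 * pi * 100^2 / 1e8 ~ 0.314
  set.seed(99)
  nodes <- tibble::tibble(id = as.character(1:4000),
                          x = runif(4000, 200, 9800), y = runif(4000, 200, 9800),
                          count_total = 1L)
  feats <- build_features(nodes, e1)
  expect_equal(mean(feats$Num_nearest_busstops), 1000 * pi * 100^2 / 1e8,
               tolerance = 0.15)
  # empty layers are refused downstream with the layer named
  empty <- make_env_layers(ext, c(greenspace = 0, waterbody = 5, busstop = 10), 1L)
  expect_error(build_features(nodes, empty), "greenspace")
})
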