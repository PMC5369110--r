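test_that("non-commuting rate follows its definition and flags undefined areas", {
  agg <- tibble::tibble(area_id = c("a", "b", "c"),
                        num_non_act = c(3L, 0L, 0L),
                        num_com_act = c(1L, 9L, 0L))
  r <- noncommuting_rate(agg)
  expect_equal(r$rate_non_act, c(0.75, 0, NA))
  expect_error(noncommuting_rate(tibble::tibble(area_id = "a", num_non_act = -1L,
                                                num_com_act = 0L)),
               "non-negative")
  # the single-area rate from aggregate activity totals
  tot <- noncommuting_rate(tibble::tibble(area_id = "city", num_non_act = 113075L,
                                          num_com_act = 174758L))
  expect_equal(tot$rate_non_act, 113075 / 287833, tolerance = 1e-12)
})

test_that("Gi* reproduces hand evaluations and degenerate-input errors", {
  ctx <- gi_context(c("a", "b", "c", "d"), c(0, 0, 0, 4))
  expect_equal(gi_star("d", ctx), 3 / sqrt(3), tolerance = 1e-12)
  expect_equal(gi_star(c("a", "d"), ctx), 1, tolerance = 1e-12)
  # region whose value sum equals n * xbar has G* = 0
  ctx2 <- gi_context(c("a", "b", "c", "d"), c(1, 3, 2, 2))
  expect_equal(gi_star(c("a", "b"), ctx2), 0)
  expect_error(gi_star(c("a", "b", "c", "d"), ctx), "proper subset")
  expect_error(gi_star("a", gi_context(c("a", "b"), c(2, 2))), "constant")
})

test_that("ecotope growth matches exhaustive evaluation on strips", {
  s3 <- strip_partition(3)
  adj3 <- build_adjacency(s3)
  ctx3 <- gi_context(s3$id, c(0, 10, 0))
  expect_equal(grow_ecotope(s3$id[2], "high", ctx3, adj3), s3$id[2])
  s4 <- strip_partition(4)
  adj4 <- build_adjacency(s4)
  ctx4 <- gi_context(s4$id, c(9, 10, 0, 0))
  expect_setequal(grow_ecotope(s4$id[2], "high", ctx4, adj4), s4$id[1:2])
  expect_error(grow_ecotope(s4$id[1], "high",
                            gi_context(s4$id, rep(2, 4)), adj4),
               "constant")
})

test_that("negating centred values swaps high and low ecotopes exactly", {
  set.seed(21)
  lat <- lattice_partition(4, 4)
  adj <- build_adjacency(lat)
  x <- runif(16)
  ctx_pos <- gi_context(lat$id, x)
  ctx_neg <- gi_context(lat$id, 2 * mean(x) - x)
  for (sd_id in lat$id[c(1, 6, 11, 16)]) {
    expect_setequal(grow_ecotope(sd_id, "high", ctx_pos, adj),
                    grow_ecotope(sd_id, "low", ctx_neg, adj))
    expect_setequal(grow_ecotope(sd_id, "low", ctx_pos, adj),
                    grow_ecotope(sd_id, "high", ctx_neg, adj))
  }
})

test_that("permutation p-values hit their bounds and detect a planted extreme region", {
  # observed |G*| = 0: every permutation ties or exceeds -> p = 1
  ctx <- gi_context(c("a", "b", "c", "d"), c(1, 3, 2, 2))
  expect_equal(permutation_pvalue(c("a", "b"), ctx, n_perm = 999L, seed = 1L), 1)
  # planted extreme region (all maximal values) in a 10x10 lattice
  lat <- lattice_partition(10, 10)
  set.seed(14)
  vals <- runif(100)
  planted <- c("a001_001", "a001_002", "a002_001", "a002_002")
  vals[match(planted, lat$id)] <- 5
  ctx100 <- gi_context(lat$id, vals)
  p <- permutation_pvalue(planted, ctx100, n_perm = 999L, seed = 2L)
  expect_lte(p, 0.01)
  expect_equal(p, 1 / 1000)   # larger than every permuted value
})

test_that("run_amoeba labels solutions per the cluster-type convention", {
  expect_equal(classify_solution(c(2L, 0L, -3L, 1L, -1L)),
               c("high", "outside", "low", "high", "low"))
  # constant rates: no cluster is significant, all solution values 0
  lat <- lattice_partition(3, 3)
  adj <- build_adjacency(lat)
  rates <- tibble::tibble(area_id = lat$id, rate_non_act = 0.5)
  expect_warning(res <- run_amoeba(rates, adj, alpha = 0.01, n_perm = 99L, seed = 1L),
                 "minimum attainable")
  expect_true(all(res$areas$solution_value == 0L))
  expect_equal(nrow(res$ecotopes), 0L)
  # undefined rates are excluded and reported
  rates$rate_non_act[5] <- NA
  res2 <- run_amoeba(rates, adj, alpha = 0.05, n_perm = 99L, seed = 1L)
  expect_equal(res2$excluded_area_ids, lat$id[5])
  expect_equal(nrow(res2$areas), 8L)
  expect_error(suppressWarnings(run_amoeba(rates[5, ], adj, n_perm = 99L)), "at least 2")
})

test_that("reported ecotopes are disjoint and solution signs match directions", {
  b <- generate_study(small_sim_config(seed = 9L))
  nodes <- infer_noncommute(clean_nodes(b$nodes)$kept)
  rates <- noncommuting_rate(aggregate_to_areas(nodes, b$node_area, b$areas$id))
  res <- run_amoeba(rates[, c("area_id", "rate_non_act")],
                    build_adjacency(b$areas), alpha = 0.05, n_perm = 99L, seed = 3L)
  all_members <- unlist(res$ecotopes$area_ids)
  expect_equal(anyDuplicated(all_members), 0L)
  if (nrow(res$ecotopes) > 0) {
    expect_true(all(res$ecotopes$p_value < 0.05))
    expect_true(all(sign(res$ecotopes$solution_value) ==
                      ifelse(res$ecotopes$direction == "high", 1, -1)))
    expect_true(all(abs(res$ecotopes$gi_star[res$ecotopes$direction == "high"]) ==
                      res$ecotopes$gi_star[res$ecotopes$direction == "high"]))
  }
  # per-area labels agree with ecotope membership
  td <- tidy(res)
  for (i in seq_len(nrow(res$ecotopes))) {
    members <- res$ecotopes$area_ids[[i]]
    expect_true(all(td$solution_value[match(members, td$area_id)] ==
                      res$ecotopes$solution_value[i]))
  }
})

test_that("greedy growth never exceeds the brute-force contiguous optimum (small oracle)", {
  lat <- lattice_partition(2, 3)
  adj <- build_adjacency(lat)
  set.seed(33)
  for (rep in 1:20) {
    vals <- sample(0:3, 6, replace = TRUE)
    if (sd(vals) == 0) next
    ctx <- gi_context(lat$id, vals)
    seed_id <- lat$id[which.max(vals)]
    greedy <- gi_star(grow_ecotope(seed_id, "high", ctx, adj), ctx)
    oracle <- brute_force_best_gi(ctx, adj, seed_id, "high")
    expect_lte(greedy, oracle + 1e-12)
  }
})
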