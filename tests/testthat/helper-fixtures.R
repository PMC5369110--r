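# Fixture builders shared across test files. All fixtures are constructed in
# code; nothing is read from disk except temp files the tests write.

strip_partition <- function(n) make_area_partition(c(0, n, 0, 1), c(1, n))

lattice_partition <- function(rows, cols) {
  make_area_partition(c(0, cols, 0, rows), c(rows, cols))
}

make_test_nodes <- function(total, commute, x = NULL, y = NULL) {
  n <- length(total)
  tibble::tibble(
    id = sprintf("n%03d", seq_len(n)),
    x = x %||% rep(0.5, n), y = y %||% rep(0.5, n),
    count_total = as.integer(total), count_commute = as.integer(commute)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent oracle: maximal (direction-signed) Gi* over ALL contiguous
# subsets of the study region that contain the seed, by exhaustive
# enumeration. Only feasible for tiny lattices.
brute_force_best_gi <- function(context, adjacency, seed_id, direction) {
  ids <- context$ids
  n <- length(ids)
  sgn <- if (direction == "high") 1 else -1
  seed_pos <- match(seed_id, ids)
  is_contiguous <- function(members) {
    if (length(members) == 1L) return(TRUE)
    visited <- members[1]
    frontier <- members[1]
    while (length(frontier) > 0L) {
      nxt <- setdiff(intersect(unlist(adjacency[frontier]), members), visited)
      visited <- c(visited, nxt)
      frontier <- nxt
    }
    length(visited) == length(members)
  }
  best <- -Inf
  for (mask in seq_len(2^n - 1)) {
    members <- ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (!(ids[seed_pos] %in% members) || length(members) >= n) next
    if (!is_contiguous(members)) next
    g <- sgn * gi_star(members, context)
    if (g > best) best <- g
  }
  best
}

# small, fast study used by several end-to-end tests
small_sim_config <- function(seed = 1L, ...) {
  args <- list(
    seed = seed,
    extent = c(0, 4000, 0, 4000),
    n_nodes = 800L,
    area_grid_shape = c(8L, 8L),
    pm_cell_size = 1000,
    planted_regions = list(list(region = rect_ring(500, 1500, 2500, 3500),
                                share = 0.2)),
    env_counts = c(greenspace = 20, waterbody = 10, busstop = 150)
  )
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(sim_config, args)
}
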