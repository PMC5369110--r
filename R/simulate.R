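# Synthetic-study generator. Emulates the structure of intersection-level
# crowdsourced cycling counts: exponential-tailed activity totals, a
# commuting share that varies with distance to the city centre (optionally
# overridden inside planted regions), a declining city-centre PM gradient on
# a 1 km grid, scattered environment point layers, and a small fraction of
# invalid records. Ground truth (planted membership, per-node shares,
# corrupted ids) is carried alongside for recovery tests.

#' Deterministic sub-seed for a named random stream
#'
#' All randomness in a simulated study flows from one root seed; each layer
#' (node placement, counts, noise injection, PM field, environment points,
#' purpose noise) draws from its own stream so partial regenerations are
#' reproducible.
#'
#' @param seed Integer root seed.
#' @param stream Small integer stream index.
#' @return An integer seed below 2^31.
#' @export
split_seed <- function(seed, stream) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + 1009 * stream) %% 2147483647)
}

.STREAMS <- c(nodes = 1L, counts = 2L, noise = 3L, env = 4L, pm = 5L, purpose = 6L)

#' Simulation configuration
#'
#' Defaults define the package's reference study: a 10 km x 10 km city on a
#' 20 x 20 areal partition with 5,000 intersections, a geometric
#' (discrete-exponential) activity-count law, a uniform background commuting
#' share of 0.6 with one planted region where the share is 0.2, a PM surface
#' decaying from the centre, and 2% invalid node records.
#'
#' @param seed Integer root seed.
#' @param extent `c(xmin, xmax, ymin, ymax)` in projected meters.
#' @param n_nodes Number of intersections.
#' @param area_grid_shape `c(rows, cols)` rectangular areal partition.
#' @param pm_cell_size Pollutant grid cell side, meters.
#' @param count_tail_rate Rate of the exponential tail of activity totals;
#'   totals are geometric with success probability `1 - exp(-rate)`,
#'   conditioned to be at least 1.
#' @param commute_share_centre,commute_share_edge Commuting share at the city
#'   centre and at the maximal distance from it; interpolated linearly in
#'   distance.
#' @param planted_regions List of `list(region = <ring>, share = <prob>)`;
#'   inside a planted region the commuting share is replaced by `share`.
#' @param noise_node_fraction Fraction of nodes corrupted into invalid
#'   records (zero totals / commuting above total).
#' @param pm10_base,pm10_amplitude,pm10_decay_scale PM10 field:
#'   `base + amplitude * exp(-d / scale)` (micrograms/m^3; scale in meters).
#' @param pm25_ratio PM2.5 as a fraction of PM10, in (0, 1].
#' @param pm_noise_sd Gaussian noise s.d. added independently to each
#'   pollutant, micrograms/m^3 (fields truncated at 0).
#' @param env_counts Named vector `c(greenspace=, waterbody=, busstop=)`.
#' @param purpose_model Optional planted estimation relationship:
#'   `list(coefficients = c(intercept, num_cycling, dis_greenspace,
#'   dis_waterbody, dis_citycentre, num_busstops), noise_sd = 0)`. When set,
#'   the non-commuting count is this (rounded, clamped to `[0, total]`)
#'   function of the total and the locational features instead of a binomial
#'   draw, so estimation models can be tested against an exact truth.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       extent = c(0, 10000, 0, 10000),
                       n_nodes = 5000L,
                       area_grid_shape = c(20L, 20L),
                       pm_cell_size = 1000,
                       count_tail_rate = 0.2,
                       commute_share_centre = 0.6,
                       commute_share_edge = 0.6,
                       planted_regions = list(
                         list(region = rect_ring(1000, 4000, 6000, 9000), share = 0.2)
                       ),
                       noise_node_fraction = 0.02,
                       pm10_base = 10,
                       pm10_amplitude = 5,
                       pm10_decay_scale = 3000,
                       pm25_ratio = 0.75,
                       pm_noise_sd = 0.3,
                       env_counts = c(greenspace = 50, waterbody = 20, busstop = 1000),
                       purpose_model = NULL) {
  cfg <- list(seed = as.integer(seed), extent = as.numeric(extent),
              n_nodes = as.integer(n_nodes),
              area_grid_shape = as.integer(area_grid_shape),
              pm_cell_size = pm_cell_size, count_tail_rate = count_tail_rate,
              commute_share_centre = commute_share_centre,
              commute_share_edge = commute_share_edge,
              planted_regions = planted_regions,
              noise_node_fraction = noise_node_fraction,
              pm10_base = pm10_base, pm10_amplitude = pm10_amplitude,
              pm10_decay_scale = pm10_decay_scale, pm25_ratio = pm25_ratio,
              pm_noise_sd = pm_noise_sd, env_counts = env_counts,
              purpose_model = purpose_model)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  ex <- cfg$extent
  if (length(ex) != 4L || ex[2] <= ex[1] || ex[4] <= ex[3]) {
    abort("degenerate extent: need c(xmin, xmax, ymin, ymax) with positive spans")
  }
  if (cfg$n_nodes < 1L) abort("n_nodes must be positive")
  if (any(cfg$area_grid_shape < 1L)) abort("area_grid_shape must be positive")
  if (cfg$count_tail_rate <= 0) abort("count_tail_rate must be > 0")
  probs <- c(cfg$commute_share_centre, cfg$commute_share_edge,
             vapply(cfg$planted_regions, function(r) r$share, numeric(1)))
  if (any(probs < 0 | probs > 1)) abort("commute shares must lie in [0, 1]")
  if (cfg$noise_node_fraction < 0 || cfg$noise_node_fraction >= 1) {
    abort("noise_node_fraction must lie in [0, 1)")
  }
  if (cfg$pm25_ratio <= 0 || cfg$pm25_ratio > 1) abort("pm25_ratio must lie in (0, 1]")
  if (cfg$pm_cell_size <= 0) abort("pm_cell_size must be positive")
  invisible(cfg)
}

#' Rectangular areal partition of an extent
#'
#' A rows x cols grid of rectangles standing in for irregular census output
#' areas: contiguous by construction with a known queen adjacency.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)`.
#' @param shape `c(rows, cols)`.
#' @return Area tibble: `id`, `centre_x`, `centre_y`, `geometry` list-column.
#' @export
make_area_partition <- function(extent, shape) {
  rows <- shape[1]; cols <- shape[2]
  dx <- (extent[2] - extent[1]) / cols
  dy <- (extent[4] - extent[3]) / rows
  grid <- expand.grid(row = seq_len(rows), col = seq_len(cols))
  grid <- grid[order(grid$row, grid$col), ]
  tibble(
    id = sprintf("a%03d_%03d", grid$row, grid$col),
    centre_x = extent[1] + (grid$col - 0.5) * dx,
    centre_y = extent[3] + (grid$row - 0.5) * dy,
    geometry = map2(grid$row, grid$col, function(r, cl) {
      rect_ring(extent[1] + (cl - 1) * dx, extent[1] + cl * dx,
                extent[3] + (r - 1) * dy, extent[3] + r * dy)
    })
  )
}

#' Square pollutant grid covering an extent
#'
#' @param extent `c(xmin, xmax, ymin, ymax)`.
#' @param cell_size Cell side, meters.
#' @return Cell tibble: `id`, `centre_x`, `centre_y`, `size`, `geometry`.
#' @export
make_pm_grid <- function(extent, cell_size) {
  nx <- ceiling((extent[2] - extent[1]) / cell_size)
  ny <- ceiling((extent[4] - extent[3]) / cell_size)
  grid <- expand.grid(iy = seq_len(ny), ix = seq_len(nx))
  grid <- grid[order(grid$iy, grid$ix), ]
  tibble(
    id = sprintf("g%03d_%03d", grid$iy, grid$ix),
    centre_x = extent[1] + (grid$ix - 0.5) * cell_size,
    centre_y = extent[3] + (grid$iy - 0.5) * cell_size,
    size = cell_size,
    geometry = map2(grid$ix, grid$iy, function(ix, iy) {
      rect_ring(extent[1] + (ix - 1) * cell_size, extent[1] + ix * cell_size,
                extent[3] + (iy - 1) * cell_size, extent[3] + iy * cell_size)
    })
  )
}

#' Annual-mean PM surface with a city-centre gradient
#'
#' `pm10 = base + amplitude * exp(-d / scale) + noise` (truncated at 0), with
#' `d` the distance from the cell centroid to the city centre;
#' `pm25 = pm25_ratio * pm10 + independent noise` (truncated at 0). This is
#' the package's emulation of modelled background pollutant maps whose
#' levels decline from the city centre toward the outskirts.
#'
#' @param cells Cell tibble from [make_pm_grid()].
#' @param centre `c(x, y)` city-centre point.
#' @param pm_params List with `pm10_base`, `pm10_amplitude`,
#'   `pm10_decay_scale`, `pm25_ratio`, `pm_noise_sd`.
#' @param seed Integer seed for the noise stream.
#' @return `cells` with `pm10` and `pm25` columns appended.
#' @export
make_pm_surface <- function(cells, centre, pm_params, seed = 0L) {
  p <- pm_params
  if (p$pm10_decay_scale <= 0) abort("pm10_decay_scale must be > 0")
  d <- sqrt((cells$centre_x - centre[1])^2 + (cells$centre_y - centre[2])^2)
  set.seed(seed)
  n <- nrow(cells)
  noise10 <- if (p$pm_noise_sd > 0) stats::rnorm(n, 0, p$pm_noise_sd) else numeric(n)
  noise25 <- if (p$pm_noise_sd > 0) stats::rnorm(n, 0, p$pm_noise_sd) else numeric(n)
  pm10 <- pmax(0, p$pm10_base + p$pm10_amplitude * exp(-d / p$pm10_decay_scale) + noise10)
  pm25 <- pmax(0, p$pm25_ratio * pm10 + noise25)
  mutate(cells, pm10 = pm10, pm25 = pm25)
}

# commuting share at distance d from the centre: linear interpolation between
# the centre and edge shares, replaced by the planted share inside a region
.commute_share_at <- function(x, y, cfg) {
  ex <- cfg$extent
  centre <- c((ex[1] + ex[2]) / 2, (ex[3] + ex[4]) / 2)
  dmax <- sqrt((ex[2] - centre[1])^2 + (ex[4] - centre[2])^2)
  d <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
  share <- cfg$commute_share_centre +
    (cfg$commute_share_edge - cfg$commute_share_centre) * pmin(d / dmax, 1)
  for (pr in cfg$planted_regions) {
    ring <- as_ring(pr$region)
    inside <- vapply(seq_along(x), function(i) {
      point_in_polygon(x[i], y[i], ring) != "outside"
    }, logical(1))
    share[inside] <- pr$share
  }
  pmin(1, pmax(0, share))
}

#' Draw activity counts for nodes
#'
#' Totals follow a geometric law (the discrete analog of an exponential
#' tail) conditioned to be at least 1, with success probability
#' `1 - exp(-count_tail_rate)`; the commuting count is a binomial split of
#' the total with the location-dependent commuting share. The per-node share
#' actually used is returned as ground truth.
#'
#' @param nodes Tibble with `id`, `x`, `y` inside the configured extent.
#' @param config A [sim_config()].
#' @param seed Integer seed for the count stream.
#' @return List: `nodes` (with `count_total`, `count_commute`) and
#'   `true_share` (per-node commuting share).
#' @export
sample_node_counts <- function(nodes, config, seed = 0L) {
  set.seed(seed)
  n <- nrow(nodes)
  p_geom <- 1 - exp(-config$count_tail_rate)
  total <- 1L + stats::rgeom(n, p_geom)
  share <- .commute_share_at(nodes$x, nodes$y, config)
  commute <- stats::rbinom(n, total, share)
  list(
    nodes = mutate(nodes, count_total = as.integer(total),
                   count_commute = as.integer(commute)),
    true_share = share
  )
}

#' Corrupt a fraction of nodes into invalid records
#'
#' `floor(fraction * n)` randomly chosen nodes are corrupted: the first half
#' (rounded up) get a zero total, the rest a commuting count exceeding the
#' total — the two invalidity classes the cleaning step removes.
#'
#' @param nodes Node tibble with counts.
#' @param fraction Fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return List: `nodes` (corrupted table) and `corrupted_ids`.
#' @export
inject_noise_nodes <- function(nodes, fraction, seed = 0L) {
  if (fraction < 0 || fraction >= 1) abort("noise fraction must lie in [0, 1)")
  m <- floor(fraction * nrow(nodes))
  if (m == 0L) return(list(nodes = nodes, corrupted_ids = character(0)))
  set.seed(seed)
  idx <- sample.int(nrow(nodes), m)
  n_zero <- ceiling(m / 2)
  zero_idx <- idx[seq_len(n_zero)]
  over_idx <- idx[setdiff(seq_len(m), seq_len(n_zero))]
  nodes$count_total[zero_idx] <- 0L
  nodes$count_commute[zero_idx] <- 0L
  nodes$count_commute[over_idx] <- nodes$count_total[over_idx] + 1L
  list(nodes = nodes, corrupted_ids = as.character(nodes$id[sort(idx)]))
}

#' Scatter environment point layers over the extent
#'
#' Uniform point sets for greenspace, waterbody and bus stops, plus a fixed
#' city-centre point at the extent centre.
#'
#' @param extent `c(xmin, xmax, ymin, ymax)`.
#' @param env_counts Named counts `c(greenspace=, waterbody=, busstop=)`.
#' @param seed Integer seed.
#' @return EnvLayers list: tibbles `greenspace`, `waterbody`, `busstop`
#'   (columns `x`, `y`) and `city_centre = c(x, y)`.
#' @export
make_env_layers <- function(extent, env_counts, seed = 0L) {
  if (any(env_counts < 0)) abort("env_counts must be non-negative")
  set.seed(seed)
  scatter <- function(k) {
    k <- as.integer(k)
    tibble(x = stats::runif(k, extent[1], extent[2]),
           y = stats::runif(k, extent[3], extent[4]))
  }
  list(
    greenspace = scatter(env_counts[["greenspace"]]),
    waterbody = scatter(env_counts[["waterbody"]]),
    busstop = scatter(env_counts[["busstop"]]),
    city_centre = c((extent[1] + extent[2]) / 2, (extent[3] + extent[4]) / 2)
  )
}

#' Generate a complete synthetic study
#'
#' Produces nodes with activity counts (including injected invalid records),
#' a contiguous areal partition, a PM grid covering the extent, environment
#' point layers, node-to-area and node-to-cell assignments, and the
#' generative ground truth. Deterministic given the configuration.
#'
#' @param config A [sim_config()].
#' @return A `study_bundle`: list with `nodes`, `areas`, `pm_cells`,
#'   `env_layers`, `node_area` and `node_cell` assignment tibbles, `truth`
#'   (planted area ids, per-node true share, purpose coefficients, corrupted
#'   ids) and the `config`.
#' @export
generate_study <- function(config) {
  validate_sim_config(config)
  ex <- config$extent
  seed <- config$seed

  areas <- make_area_partition(ex, config$area_grid_shape)
  env <- make_env_layers(ex, config$env_counts, split_seed(seed, .STREAMS[["env"]]))

  set.seed(split_seed(seed, .STREAMS[["nodes"]]))
  n <- config$n_nodes
  nodes <- tibble(
    id = sprintf("n%06d", seq_len(n)),
    x = stats::runif(n, ex[1], ex[2]),
    y = stats::runif(n, ex[3], ex[4])
  )

  drawn <- sample_node_counts(nodes, config, split_seed(seed, .STREAMS[["counts"]]))
  nodes <- drawn$nodes
  true_share <- drawn$true_share

  # planted purpose relationship: overwrite the binomial split with a
  # deterministic (plus optional gaussian) function of total and features
  if (!is.null(config$purpose_model)) {
    feats <- build_features(nodes, env)
    b <- config$purpose_model$coefficients
    stopifnot(length(b) == 6L)
    mu <- b[1] + b[2] * feats$Num_cycling + b[3] * feats$Dis_to_Greenspace +
      b[4] * feats$Dis_to_Waterbody + b[5] * feats$Dis_to_Citycentre +
      b[6] * feats$Num_nearest_busstops
    noise_sd <- config$purpose_model$noise_sd %||% 0
    if (noise_sd > 0) {
      set.seed(split_seed(seed, .STREAMS[["purpose"]]))
      mu <- mu + stats::rnorm(n, 0, noise_sd)
    }
    noncom <- pmin(nodes$count_total, pmax(0L, as.integer(round(mu))))
    nodes$count_commute <- as.integer(nodes$count_total - noncom)
    true_share <- ifelse(nodes$count_total > 0,
                         nodes$count_commute / nodes$count_total, NA_real_)
  }

  corrupted <- inject_noise_nodes(nodes, config$noise_node_fraction,
                                  split_seed(seed, .STREAMS[["noise"]]))
  nodes <- corrupted$nodes

  pm_cells <- make_pm_grid(ex, config$pm_cell_size)
  pm_cells <- make_pm_surface(
    pm_cells, env$city_centre,
    config[c("pm10_base", "pm10_amplitude", "pm10_decay_scale",
             "pm25_ratio", "pm_noise_sd")],
    split_seed(seed, .STREAMS[["pm"]])
  )

  node_area <- assign_points_to_polygons(nodes, areas)
  node_cell <- assign_points_to_polygons(nodes, pm_cells)

  planted_area_ids <- character(0)
  for (pr in config$planted_regions) {
    ring <- as_ring(pr$region)
    inside <- vapply(seq_len(nrow(areas)), function(i) {
      point_in_polygon(areas$centre_x[i], areas$centre_y[i], ring) != "outside"
    }, logical(1))
    planted_area_ids <- union(planted_area_ids, areas$id[inside])
  }

  structure(list(
    nodes = nodes,
    areas = areas,
    pm_cells = pm_cells,
    env_layers = env,
    node_area = node_area,
    node_cell = node_cell,
    truth = list(
      planted_area_ids = sort(planted_area_ids),
      true_commute_share = tibble(id = nodes$id, share = true_share),
      purpose_model = config$purpose_model,
      corrupted_ids = corrupted$corrupted_ids
    ),
    config = config
  ), class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n")
  cat(sprintf("  nodes: %d (%d corrupted)\n", nrow(x$nodes),
              length(x$truth$corrupted_ids)))
  cat(sprintf("  areas: %d  pm cells: %d\n", nrow(x$areas), nrow(x$pm_cells)))
  cat(sprintf("  planted areas: %d  seed: %d\n",
              length(x$truth$planted_area_ids), x$config$seed))
  invisible(x)
}
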