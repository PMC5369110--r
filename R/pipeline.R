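# End-to-end pipeline: simulate (or load) -> clean -> aggregate/rates ->
# clusters -> exposure -> estimation, with every artifact persisted as
# CSV/GeoJSON and a JSON run manifest capturing the config, consumed seeds
# and stage row counts. Identical configs reproduce identical outputs.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] to simulate inputs, or `NULL` to read them
#'   from `paths`.
#' @param paths Named list of input paths (`nodes`, `areas`, `pm_cells`,
#'   `env_layers`) when not simulating.
#' @param alpha Cluster significance threshold (default 0.01).
#' @param n_perm Permutations per candidate ecotope (default 999).
#' @param pm10_guideline,pm25_guideline WHO annual guidelines,
#'   micrograms/m^3 (defaults 20 and 10).
#' @param band_edges_pm10,band_edges_pm25 Pollutant band edges for the
#'   cluster crosstabs.
#' @param k Cross-validation folds (default 10).
#' @param models Estimation model kinds to run.
#' @param seed Root seed for every random stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            paths = NULL,
                            alpha = 0.01,
                            n_perm = 999L,
                            pm10_guideline = WHO_PM10_GUIDELINE,
                            pm25_guideline = WHO_PM25_GUIDELINE,
                            band_edges_pm10 = c(0, 10, 12, 14, Inf),
                            band_edges_pm25 = c(0, 8, 9, 10, Inf),
                            k = 10L,
                            models = MODEL_KINDS,
                            seed = 1L) {
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (pm10_guideline <= 0 || pm25_guideline <= 0) abort("guidelines must be positive")
  if (is.unsorted(band_edges_pm10, strictly = TRUE) ||
      is.unsorted(band_edges_pm25, strictly = TRUE)) {
    abort("band edges must be strictly increasing")
  }
  structure(list(sim = sim, paths = paths, alpha = alpha,
                 n_perm = as.integer(n_perm),
                 pm10_guideline = pm10_guideline, pm25_guideline = pm25_guideline,
                 band_edges_pm10 = band_edges_pm10, band_edges_pm25 = band_edges_pm25,
                 k = as.integer(k), models = models, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim` block
#' mirrors [sim_config()] (planted regions as
#' `{xmin, xmax, ymin, ymax, share}` rectangles).
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  sim <- NULL
  if (!is.null(raw$sim)) {
    s <- raw$sim
    if (!is.null(s$planted_regions)) {
      s$planted_regions <- lapply(seq_along(s$planted_regions), function(i) {
        pr <- if (is.data.frame(s$planted_regions)) as.list(s$planted_regions[i, ])
              else s$planted_regions[[i]]
        list(region = rect_ring(pr$xmin, pr$xmax, pr$ymin, pr$ymax),
             share = pr$share)
      })
    }
    if (!is.null(s$env_counts)) s$env_counts <- unlist(s$env_counts)
    sim <- do.call(sim_config, s)
  }
  args <- raw[setdiff(names(raw), "sim")]
  args$sim <- sim
  do.call(pipeline_config, args)
}

.write_csv <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) if (is.list(df[[col]])) {
    df[[col]] <- vapply(df[[col]], function(v) paste(v, collapse = ";"), character(1))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, cleaning, aggregation and rates, AMOEBA cluster
#' detection, the exposure report and the estimation comparison, writing
#' every stage's output plus a `manifest.json` into `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds_used <- list()

  # ---- inputs ----
  if (is.null(config$sim)) {
    need <- c("nodes", "areas", "pm_cells", "env_layers")
    missing <- setdiff(need, names(config$paths))
    if (length(missing) > 0L) {
      abort(sprintf("[input] config lacks input path(s): %s",
                    paste(missing, collapse = ", ")))
    }
    for (p in unlist(config$paths[need])) {
      if (!file.exists(p)) abort(sprintf("[input] input path does not exist: %s", p))
    }
    say("input", "reading input layers")
    nodes <- read_nodes(config$paths$nodes)
    areas <- read_polygons(config$paths$areas)
    if (!"centre_x" %in% names(areas)) {
      cent <- t(vapply(areas$geometry, function(r) colMeans(as_ring(r)), numeric(2)))
      areas$centre_x <- cent[, 1]; areas$centre_y <- cent[, 2]
    }
    pm_cells <- read_pm_cells(config$paths$pm_cells)
    env <- read_env_layers(config$paths$env_layers)
    bundle <- list(nodes = nodes, areas = areas, pm_cells = pm_cells,
                   env_layers = env,
                   node_area = assign_points_to_polygons(nodes, areas),
                   node_cell = assign_points_to_polygons(nodes, pm_cells),
                   truth = NULL, config = NULL)
  } else {
    sim_cfg <- config$sim
    sim_cfg$seed <- config$seed
    say("simulate", "generating study (seed %d, %d nodes)", config$seed, sim_cfg$n_nodes)
    bundle <- generate_study(sim_cfg)
    seeds_used$simulation <- lapply(as.list(.STREAMS), function(s) split_seed(config$seed, s))
    write_nodes(bundle$nodes, file.path(out_dir, "nodes_raw.csv"))
    write_polygons(bundle$areas %>% select("id", "geometry"),
                   file.path(out_dir, "areas.geojson"))
    write_pm_cells(bundle$pm_cells, file.path(out_dir, "pm_cells.csv"))
    write_env_layers(bundle$env_layers, file.path(out_dir, "env_layers.geojson"))
    .write_csv(tibble(area_id = bundle$truth$planted_area_ids),
               file.path(out_dir, "truth_planted_areas.csv"))
    .write_csv(bundle$truth$true_commute_share, file.path(out_dir, "truth_node_share.csv"))
  }

  # ---- clean ----
  cleaned <- clean_nodes(bundle$nodes)
  nodes <- infer_noncommute(cleaned$kept)
  say("clean", "%d nodes kept, %d removed", nrow(nodes), nrow(cleaned$removed))
  write_nodes(nodes, file.path(out_dir, "nodes_clean.csv"))
  if (nrow(cleaned$removed) > 0) {
    write_nodes(cleaned$removed, file.path(out_dir, "nodes_removed.csv"))
  }

  # ---- rates ----
  agg <- aggregate_to_areas(nodes, bundle$node_area, bundle$areas$id)
  rates <- noncommuting_rate(agg)
  say("rates", "%d areas, %d with activities", nrow(rates),
      sum(!is.na(rates$rate_non_act)))
  .write_csv(rates, file.path(out_dir, "area_rates.csv"))

  # ---- clusters ----
  adjacency <- build_adjacency(bundle$areas)
  cl_seed <- split_seed(config$seed, 7L)
  seeds_used$clusters <- cl_seed
  clusters <- run_amoeba(rates %>% select("area_id", "rate_non_act"), adjacency,
                         alpha = config$alpha, n_perm = config$n_perm,
                         seed = cl_seed)
  say("clusters", "%d high / %d low ecotopes kept",
      sum(clusters$ecotopes$direction == "high"),
      sum(clusters$ecotopes$direction == "low"))
  .write_csv(tidy(clusters), file.path(out_dir, "clusters_areas.csv"))
  .write_csv(clusters$ecotopes, file.path(out_dir, "clusters_ecotopes.csv"))

  # ---- exposure ----
  bundle_clean <- bundle
  bundle_clean$nodes <- nodes
  exposure <- exposure_report(bundle_clean, clusters,
                              pm25_guideline = config$pm25_guideline,
                              pm10_guideline = config$pm10_guideline,
                              band_edges_pm10 = config$band_edges_pm10,
                              band_edges_pm25 = config$band_edges_pm25)
  say("exposure", "means PM10 %.3f/%.3f, PM2.5 %.3f/%.3f (non/com)",
      exposure$summary$mean_pm10_non, exposure$summary$mean_pm10_com,
      exposure$summary$mean_pm25_non, exposure$summary$mean_pm25_com)
  .write_csv(exposure$summary, file.path(out_dir, "exposure_summary.csv"))
  .write_csv(exposure$band_pm10, file.path(out_dir, "band_pm10.csv"))
  .write_csv(exposure$band_pm25, file.path(out_dir, "band_pm25.csv"))

  # ---- estimate ----
  feats <- build_features(nodes, bundle$env_layers)
  est_seed <- split_seed(config$seed, 8L)
  seeds_used$estimation <- est_seed
  est <- estimate_purpose(feats, nodes$count_noncommute, models = config$models,
                          k = config$k, seed = est_seed)
  say("estimate", "pooled CV r: %s",
      paste(sprintf("%s %.3f", est$result$model, est$result$pearson_r),
            collapse = ", "))
  .write_csv(est$result, file.path(out_dir, "estimation_results.csv"))
  .write_csv(est$predictions, file.path(out_dir, "estimation_predictions.csv"))

  # ---- manifest ----
  jaccard <- NULL
  if (!is.null(bundle$truth) && length(bundle$truth$planted_area_ids) > 0) {
    high <- clusters$ecotopes %>% filter(.data$direction == "high")
    detected <- unique(unlist(high$area_ids))
    truth_set <- bundle$truth$planted_area_ids
    jaccard <- length(intersect(detected, truth_set)) /
      length(union(detected, truth_set))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("cyclexposure")),
    seed = config$seed,
    seeds_used = seeds_used,
    parameters = list(alpha = config$alpha, n_perm = config$n_perm,
                      pm10_guideline = config$pm10_guideline,
                      pm25_guideline = config$pm25_guideline,
                      k = config$k, models = config$models),
    stage_rows = list(nodes_raw = nrow(bundle$nodes), nodes_clean = nrow(nodes),
                      nodes_removed = nrow(cleaned$removed), areas = nrow(rates),
                      ecotopes = nrow(clusters$ecotopes)),
    high_cluster_jaccard_vs_truth = jaccard
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")

  invisible(list(bundle = bundle, nodes = nodes, rates = rates,
                 clusters = clusters, exposure = exposure, estimation = est,
                 manifest = manifest))
}
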