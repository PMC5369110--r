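# Activity-weighted instantaneous exposure statistics by trip purpose.
#
# Each activity at a node is assigned the annual-mean pollutant concentration
# of the 1 km grid cell containing the node ("instantaneous exposure"); the
# per-purpose mean is the activity-count-weighted mean over nodes, and the
# high-exposure percentage is the activity fraction located in cells whose
# PM2.5 exceeds the WHO annual guideline (10 micrograms/m^3). The
# non-commuting vs commuting comparison uses a Wilcoxon rank-sum test on the
# activity-expanded samples, computed via weighted midranks.

WHO_PM10_GUIDELINE <- 20
WHO_PM25_GUIDELINE <- 10

.purpose_col <- function(purpose) {
  switch(match.arg(purpose, c("noncommute", "commute")),
         noncommute = "count_noncommute", commute = "count_commute")
}

#' Activity-weighted mean instantaneous exposure
#'
#' `sum_i Num_purpose(i) * PM(i) / sum_i Num_purpose(i)` over nodes carrying
#' a pollutant value.
#'
#' @param nodes_with_pm Node tibble with `count_noncommute`,
#'   `count_commute` and the pollutant column.
#' @param purpose `"noncommute"` or `"commute"`.
#' @param pollutant Name of the pollutant column (`"pm10"` or `"pm25"`).
#' @return Weighted mean in micrograms/m^3.
#' @export
#' @examples
#' nodes <- tibble::tibble(count_noncommute = c(2L, 1L),
#'                         count_commute = c(0L, 3L), pm10 = c(10, 16))
#' weighted_exposure_mean(nodes, "noncommute")   # 12
#' weighted_exposure_mean(nodes, "commute")      # 16
weighted_exposure_mean <- function(nodes_with_pm, purpose, pollutant = "pm10") {
  w <- nodes_with_pm[[.purpose_col(purpose)]]
  pm <- nodes_with_pm[[pollutant]]
  if (is.null(w) || is.null(pm)) abort("missing count or pollutant column")
  tw <- sum(w)
  if (tw <= 0) abort(sprintf("zero total %s weight: mean undefined", purpose))
  sum(w * pm) / tw
}

#' High-exposure activity percentage
#'
#' The fraction of a purpose's activities located at nodes whose grid-cell
#' annual PM2.5 strictly exceeds the guideline (cells at exactly the
#' guideline are not "high").
#'
#' @param nodes_with_pm Node tibble with purpose counts and a `pm25` column.
#' @param purpose `"noncommute"` or `"commute"`.
#' @param guideline Threshold in micrograms/m^3 (default WHO annual PM2.5
#'   guideline, 10).
#' @param pollutant Pollutant column used for the threshold (default
#'   `"pm25"`).
#' @return Proportion in `[0, 1]`.
#' @export
high_exposure_percentage <- function(nodes_with_pm, purpose,
                                     guideline = WHO_PM25_GUIDELINE,
                                     pollutant = "pm25") {
  if (guideline <= 0) abort("guideline must be positive")
  w <- nodes_with_pm[[.purpose_col(purpose)]]
  pm <- nodes_with_pm[[pollutant]]
  tw <- sum(w)
  if (tw <= 0) abort(sprintf("zero total %s weight", purpose))
  sum(w[pm > guideline]) / tw
}

#' Cross-tabulate areas by cluster type and pollutant band
#'
#' For each cluster type (high / outside / low), the percentage of areas
#' whose pollutant value falls in each half-open band `[lo, hi)`; columns
#' sum to 100%.
#'
#' @param areas_with_type Tibble with `area_id`, `cluster_type` and the
#'   pollutant value column.
#' @param pollutant Name of the value column.
#' @param band_edges Strictly increasing numeric vector of edges; bands are
#'   `[e1, e2), [e2, e3), ...` and must cover every observed value.
#' @return Tibble: `band`, then one percentage column per cluster type.
#' @export
band_crosstab <- function(areas_with_type, pollutant, band_edges) {
  if (is.unsorted(band_edges, strictly = TRUE)) {
    abort("band_edges must be strictly increasing")
  }
  vals <- areas_with_type[[pollutant]]
  if (any(vals < band_edges[1] | vals >= band_edges[length(band_edges)])) {
    abort("observed values fall outside the configured bands")
  }
  labs <- paste0("[", utils::head(band_edges, -1), ", ",
                 utils::tail(band_edges, -1), ")")
  df <- tibble(
    band = factor(labs[findInterval(vals, band_edges)], levels = labs),
    cluster_type = factor(areas_with_type$cluster_type,
                          levels = c("high", "outside", "low"))
  )
  counts <- as.matrix(table(df$band, df$cluster_type))
  pct <- sweep(counts, 2, pmax(1L, colSums(counts)), "/") * 100
  out <- as_tibble(as.data.frame.matrix(pct), rownames = "band")
  names(out) <- c("band", colnames(pct))
  out
}

# midranks, rank-sum statistic and tie counts from a weighted sample
.weighted_ranks <- function(values, w1, w2) {
  keep <- (w1 + w2) > 0
  values <- values[keep]; w1 <- w1[keep]; w2 <- w2[keep]
  agg <- tibble(v = values, w1 = as.numeric(w1), w2 = as.numeric(w2)) %>%
    group_by(.data$v) %>%
    summarise(w1 = sum(.data$w1), w2 = sum(.data$w2), .groups = "drop") %>%
    arrange(.data$v)
  wt <- agg$w1 + agg$w2
  cumw <- cumsum(wt)
  midrank <- cumw - wt + (wt + 1) / 2
  list(values = agg$v, w1 = agg$w1, w2 = agg$w2, ties = wt, midrank = midrank)
}

#' Weighted two-sample Wilcoxon rank-sum test
#'
#' The rank-sum test applied to activity-expanded samples — each value
#' repeated by its integer weight per group — computed directly from the
#' weights via midranks. For small expanded samples the permutation
#' distribution of the Mann-Whitney statistic is enumerated exactly;
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used, matching the classical large-sample rank-sum test on
#' the expanded data.
#'
#' @param values Numeric vector of distinct observation points (e.g. node PM
#'   values; duplicates are merged).
#' @param weights_group1,weights_group2 Non-negative integer weights per
#'   value (activity counts per purpose).
#' @param alternative `"less"` (group1 stochastically smaller, the default),
#'   `"greater"`, or `"two.sided"`.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) exact enumeration;
#'   default `NULL` enumerates when the expanded size is at most 20.
#' @return List: `statistic` (Mann-Whitney U of group 1), `p_value`,
#'   `alternative`, `method`.
#' @export
#' @examples
#' # {1,2,3} vs {4,5,6}: one-sided exact p = 1/20
#' weighted_rank_sum_test(1:6, c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 1, 1, 1))$p_value
weighted_rank_sum_test <- function(values, weights_group1, weights_group2,
                                   alternative = c("less", "greater", "two.sided"),
                                   exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(values) != length(weights_group1) ||
      length(values) != length(weights_group2)) {
    abort("values and weight vectors must have equal length")
  }
  if (any(weights_group1 < 0) || any(weights_group2 < 0)) {
    abort("weights must be non-negative")
  }
  n1 <- sum(weights_group1); n2 <- sum(weights_group2)
  if (n1 == 0 || n2 == 0) abort("both groups need positive total weight")
  wr <- .weighted_ranks(values, weights_group1, weights_group2)
  r1 <- sum(wr$w1 * wr$midrank)
  u <- r1 - n1 * (n1 + 1) / 2
  n <- n1 + n2
  do_exact <- if (is.null(exact)) n <= 20 else isTRUE(exact)
  if (do_exact) {
    # enumerate all assignments of group-1 slots among the expanded ranks
    ranks <- rep(wr$midrank, times = wr$w1 + wr$w2)
    combs <- utils::combn(length(ranks), n1)
    u_perm <- colSums(matrix(ranks[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    tol <- 1e-9
    p <- switch(alternative,
      less = mean(u_perm <= u + tol),
      greater = mean(u_perm >= u - tol),
      two.sided = min(1, 2 * min(mean(u_perm <= u + tol),
                                 mean(u_perm >= u - tol)))
    )
    method <- "exact enumeration"
  } else {
    z <- u - n1 * n2 / 2
    corr <- switch(alternative, two.sided = sign(z) * 0.5,
                   greater = 0.5, less = -0.5)
    sigma <- sqrt((n1 * n2 / 12) *
                    ((n + 1) - sum(wr$ties^3 - wr$ties) / (n * (n - 1))))
    if (sigma == 0) {
      # every expanded observation tied: no evidence either way
      return(list(statistic = u, p_value = 1, alternative = alternative,
                  method = "degenerate (all observations tied)"))
    }
    z <- (z - corr) / sigma
    p <- switch(alternative,
      less = stats::pnorm(z),
      greater = stats::pnorm(z, lower.tail = FALSE),
      two.sided = min(1, 2 * min(stats::pnorm(z),
                                 stats::pnorm(z, lower.tail = FALSE)))
    )
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = u, p_value = p, alternative = alternative, method = method)
}

#' Attach grid-cell pollutant values to nodes
#'
#' @param nodes Node tibble.
#' @param pm_cells Cell tibble with `id`, `pm10`, `pm25`.
#' @param node_cell Assignment tibble `(point_id, polygon_id)`; nodes outside
#'   every cell are dropped (no imputation).
#' @return Node tibble with `pm10`, `pm25` columns.
#' @export
nodes_with_pm <- function(nodes, pm_cells, node_cell) {
  nodes %>%
    inner_join(node_cell, by = c(id = "point_id")) %>%
    filter(!is.na(.data$polygon_id)) %>%
    inner_join(pm_cells %>% select("id", "pm10", "pm25") %>%
                 rename(polygon_id = "id"),
               by = "polygon_id") %>%
    select(-"polygon_id")
}

#' Full exposure comparison report
#'
#' Assembles the purpose-stratified exposure statistics of a study: weighted
#' PM10/PM2.5 means for non-commuting and commuting activities, Wilcoxon
#' rank-sum tests (one-sided "non-commuting lower" plus two-sided),
#' high-exposure percentages against the WHO PM2.5 guideline, and — when a
#' cluster solution is supplied — cluster-type by pollutant-band
#' cross-tabulations (area-level pollutant taken from the grid cell
#' containing the area centroid).
#'
#' @param bundle A `study_bundle` (or a list with `nodes`, `pm_cells`,
#'   `node_cell`, `areas`); nodes must be cleaned before calling.
#' @param cluster_solution Optional `amoeba_clusters` object.
#' @param pm25_guideline,pm10_guideline Guidelines in micrograms/m^3.
#' @param band_edges_pm10,band_edges_pm25 Band edges for the crosstabs.
#' @return An `exposure_summary` object: `$summary` tibble (means,
#'   percentages, test statistics), `$band_pm10`, `$band_pm25` (NULL without
#'   a cluster solution), and `$nodes_used`.
#' @export
exposure_report <- function(bundle, cluster_solution = NULL,
                            pm25_guideline = WHO_PM25_GUIDELINE,
                            pm10_guideline = WHO_PM10_GUIDELINE,
                            band_edges_pm10 = c(0, 10, 12, 14, Inf),
                            band_edges_pm25 = c(0, 8, 9, 10, Inf)) {
  nd <- clean_nodes(bundle$nodes)$kept %>% infer_noncommute()
  nd <- nodes_with_pm(nd, bundle$pm_cells, bundle$node_cell)
  if (nrow(nd) == 0L) abort("no nodes fall inside a pollutant grid cell")

  means <- list(
    mean_pm10_non = weighted_exposure_mean(nd, "noncommute", "pm10"),
    mean_pm10_com = weighted_exposure_mean(nd, "commute", "pm10"),
    mean_pm25_non = weighted_exposure_mean(nd, "noncommute", "pm25"),
    mean_pm25_com = weighted_exposure_mean(nd, "commute", "pm25")
  )
  w_non <- nd$count_noncommute; w_com <- nd$count_commute
  wt10 <- weighted_rank_sum_test(nd$pm10, w_non, w_com, "less", exact = FALSE)
  wt25 <- weighted_rank_sum_test(nd$pm25, w_non, w_com, "less", exact = FALSE)
  wt10_2 <- weighted_rank_sum_test(nd$pm10, w_non, w_com, "two.sided", exact = FALSE)
  wt25_2 <- weighted_rank_sum_test(nd$pm25, w_non, w_com, "two.sided", exact = FALSE)

  summary <- tibble(
    mean_pm10_non = means$mean_pm10_non, mean_pm10_com = means$mean_pm10_com,
    mean_pm25_non = means$mean_pm25_non, mean_pm25_com = means$mean_pm25_com,
    per25_non = high_exposure_percentage(nd, "noncommute", pm25_guideline),
    per25_com = high_exposure_percentage(nd, "commute", pm25_guideline),
    wilcoxon_stat_pm10 = wt10$statistic, wilcoxon_p_pm10 = wt10$p_value,
    wilcoxon_p_pm10_two_sided = wt10_2$p_value,
    wilcoxon_stat_pm25 = wt25$statistic, wilcoxon_p_pm25 = wt25$p_value,
    wilcoxon_p_pm25_two_sided = wt25_2$p_value,
    guideline_pm10 = pm10_guideline, guideline_pm25 = pm25_guideline
  )

  band10 <- band25 <- NULL
  if (!is.null(cluster_solution)) {
    centroids <- bundle$areas %>%
      transmute(id = .data$id, x = .data$centre_x, y = .data$centre_y)
    cell_of <- assign_points_to_polygons(centroids, bundle$pm_cells)
    area_pm <- centroids %>%
      inner_join(cell_of, by = c(id = "point_id")) %>%
      filter(!is.na(.data$polygon_id)) %>%
      inner_join(bundle$pm_cells %>% select("id", "pm10", "pm25") %>%
                   rename(polygon_id = "id"), by = "polygon_id") %>%
      inner_join(tidy(cluster_solution) %>% select("area_id", "cluster_type"),
                 by = c(id = "area_id"))
    band10 <- band_crosstab(area_pm, "pm10", band_edges_pm10)
    band25 <- band_crosstab(area_pm, "pm25", band_edges_pm25)
  }

  structure(list(summary = summary, band_pm10 = band10, band_pm25 = band25,
                 nodes_used = nrow(nd)),
            class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  s <- x$summary
  cat("<exposure_summary>\n")
  cat(sprintf("  PM10 mean (ug/m^3): non-commute %.3f vs commute %.3f (one-sided p = %.3g)\n",
              s$mean_pm10_non, s$mean_pm10_com, s$wilcoxon_p_pm10))
  cat(sprintf("  PM2.5 mean (ug/m^3): non-commute %.3f vs commute %.3f (one-sided p = %.3g)\n",
              s$mean_pm25_non, s$mean_pm25_com, s$wilcoxon_p_pm25))
  cat(sprintf("  high-exposure share (PM2.5 > %g): non-commute %.1f%% vs commute %.1f%%\n",
              s$guideline_pm25, 100 * s$per25_non, 100 * s$per25_com))
  invisible(x)
}

#' Tidy view of an exposure summary
#'
#' @param x An `exposure_summary` object.
#' @param ... Unused.
#' @return Long tibble `(statistic, value)`.
#' @method tidy exposure_summary
#' @export
tidy.exposure_summary <- function(x, ...) {
  tidyr::pivot_longer(x$summary, dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}
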