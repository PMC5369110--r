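# Non-commuting rate and AMOEBA/Gi* cluster detection.
#
# The local statistic for a candidate region R inside a study region M of N
# areas with attribute x, mean xbar and population standard deviation S is
#
#   G*(R) = (sum_{i in R} x_i - n * xbar) / (S * sqrt((N*n - n^2) / (N - 1)))
#
# AMOEBA grows spatially contiguous regions (ecotopes) from each seed area,
# maximizing G* for high-value clusters and minimizing it for low-value
# clusters, and keeps regions whose permutation p-value beats the
# significance threshold.

#' Per-area non-commuting rate
#'
#' The fraction of cycling activities in an area that are non-commuting:
#' `num_non_act / (num_non_act + num_com_act)`. Undefined (NA) for areas
#' with no activities; such areas are excluded from cluster detection.
#'
#' @param area_aggregates Tibble with `area_id`, `num_non_act`, `num_com_act`.
#' @return The tibble with a `rate_non_act` column appended.
#' @export
#' @examples
#' noncommuting_rate(tibble::tibble(area_id = "a", num_non_act = 3L,
#'                                  num_com_act = 1L))$rate_non_act  # 0.75
noncommuting_rate <- function(area_aggregates) {
  stopifnot(all(c("num_non_act", "num_com_act") %in% names(area_aggregates)))
  if (any(area_aggregates$num_non_act < 0) || any(area_aggregates$num_com_act < 0)) {
    abort("activity counts must be non-negative")
  }
  denom <- area_aggregates$num_non_act + area_aggregates$num_com_act
  mutate(area_aggregates,
         rate_non_act = ifelse(denom > 0, .data$num_non_act / denom, NA_real_))
}

#' Gi* context: global moments of the attribute
#'
#' @param area_ids Character vector of area ids (the set M).
#' @param values Attribute values per area (e.g. non-commuting rates); areas
#'   with undefined values must be excluded beforehand.
#' @return A `gi_context` list with ids, values, `n_total`, `mean` and the
#'   population (divisor-N) standard deviation `sd`.
#' @export
gi_context <- function(area_ids, values) {
  area_ids <- as.character(area_ids)
  if (length(area_ids) < 2L) abort("Gi* context needs at least 2 areas")
  if (anyNA(values)) abort("undefined attribute values in Gi* context")
  if (anyDuplicated(area_ids)) abort("duplicate area ids in Gi* context")
  n <- length(values)
  xbar <- mean(values)
  s <- sqrt(sum((values - xbar)^2) / n)
  structure(list(ids = area_ids, values = stats::setNames(values, area_ids),
                 n_total = n, mean = xbar, sd = s),
            class = "gi_context")
}

#' Getis-Ord Gi* statistic of a region
#'
#' @param region_ids Ids of the areas forming the region (non-empty, proper
#'   subset of the context).
#' @param context A [gi_context()].
#' @return The Gi* value (numeric scalar).
#' @export
#' @examples
#' ctx <- gi_context(letters[1:4], c(0, 0, 0, 4))
#' gi_star("d", ctx)   # 3 / sqrt(3)
gi_star <- function(region_ids, context) {
  region_ids <- as.character(region_ids)
  n <- length(region_ids)
  N <- context$n_total
  if (n == 0L) abort("empty region")
  if (n >= N) abort("region must be a proper subset of the study region (n < N)")
  if (context$sd <= 0) abort("constant attribute: Gi* is undefined (S = 0)")
  if (!all(region_ids %in% context$ids)) abort("region contains unknown area ids")
  (sum(context$values[region_ids]) - n * context$mean) /
    (context$sd * sqrt((N * n - n^2) / (N - 1)))
}

# Gi* for region sizes n (vector) and value sums s (vector), vectorized
.gi_star_fast <- function(s, n, context) {
  N <- context$n_total
  (s - n * context$mean) / (context$sd * sqrt((N * n - n^2) / (N - 1)))
}

#' Grow an ecotope from a seed area
#'
#' Starting from the seed alone, each step sorts the region's outer
#' neighbors by attribute value (descending for `high`, ascending for
#' `low`), evaluates every prefix of that sorted list as a joint addition,
#' and adopts the prefix that most improves the region's Gi* (maximizing for
#' `high`, minimizing for `low`). Growth stops when no prefix improves the
#' current Gi*.
#'
#' @param seed_area Seed area id.
#' @param direction `"high"` or `"low"`.
#' @param context A [gi_context()].
#' @param adjacency Named list of neighbor id vectors (queen contiguity).
#' @return Character vector of member area ids (always contains the seed).
#' @export
grow_ecotope <- function(seed_area, direction = c("high", "low"),
                         context, adjacency) {
  direction <- match.arg(direction)
  seed_area <- as.character(seed_area)
  if (!seed_area %in% context$ids) abort("seed area not in context")
  if (context$sd <= 0) abort("constant attribute: Gi* is undefined (S = 0)")
  sgn <- if (direction == "high") 1 else -1
  region <- seed_area
  cur_sum <- unname(context$values[seed_area])
  cur_g <- .gi_star_fast(cur_sum, 1L, context)
  repeat {
    outer <- setdiff(unique(unlist(adjacency[region], use.names = FALSE)), region)
    outer <- outer[outer %in% context$ids]
    if (length(outer) == 0L) break
    vals <- context$values[outer]
    ord <- order(-(sgn * vals), outer)
    outer <- outer[ord]
    k_max <- min(length(outer), context$n_total - length(region) - 1L)
    if (k_max < 1L) break
    cs <- cumsum(context$values[outer])[seq_len(k_max)]
    gk <- .gi_star_fast(cur_sum + cs, length(region) + seq_len(k_max), context)
    best <- which.max(sgn * gk)
    if (sgn * gk[best] > sgn * cur_g) {
      region <- c(region, outer[seq_len(best)])
      cur_sum <- cur_sum + cs[best]
      cur_g <- gk[best]
    } else break
  }
  region
}

#' Monte-Carlo permutation p-value for a region's Gi*
#'
#' Attribute values are permuted uniformly over all areas; the region's
#' |Gi*| is recomputed under each permutation and compared with the observed
#' |Gi*|. The estimator `(1 + #{|G*_perm| >= |G*_obs|}) / (n_perm + 1)` is
#' never zero and is deterministic given the seed.
#'
#' @param region_ids Region area ids.
#' @param context A [gi_context()].
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer seed.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(region_ids, context, n_perm = 999L, seed = 0L) {
  if (n_perm < 99L) abort("n_perm must be at least 99")
  obs <- abs(gi_star(region_ids, context))
  n <- length(region_ids)
  set.seed(seed)
  # under a uniform permutation the region's value sum is the sum of a
  # uniform n-subset of the attribute values (mean and S are permutation
  # invariant)
  x <- unname(context$values)
  perm_sums <- vapply(seq_len(n_perm),
                      function(k) sum(x[sample.int(length(x), n)]), numeric(1))
  perm_g <- abs(.gi_star_fast(perm_sums, n, context))
  (1 + sum(perm_g >= obs - 1e-12)) / (n_perm + 1)
}

#' Classify an AMOEBA solution value
#'
#' @param solution_value Integer vector: positive values mark membership in
#'   a high-value cluster, negative in a low-value cluster, zero outside.
#' @return Character vector in `{"high", "outside", "low"}`.
#' @export
classify_solution <- function(solution_value) {
  dplyr::case_when(solution_value >= 1 ~ "high",
                   solution_value <= -1 ~ "low",
                   .default = "outside")
}

#' Run AMOEBA cluster detection
#'
#' Grows one candidate ecotope per area per direction, keeps candidates
#' whose permutation p-value is below `alpha`, resolves overlaps greedily by
#' descending |Gi*| (a kept ecotope excludes every later candidate sharing
#' any area), and assigns integer solution values: the k-th kept high
#' ecotope gets `+k`, the k-th kept low ecotope `-k`, everything else 0.
#' Areas with an undefined rate are excluded from the context and reported
#' separately.
#'
#' @param areas_with_rates Tibble with `area_id` and `rate_non_act`
#'   (NA = undefined, excluded).
#' @param adjacency Named list of neighbor ids from [build_adjacency()].
#' @param alpha Significance threshold (default 0.01).
#' @param n_perm Permutations per candidate (default 999).
#' @param seed Integer seed for the permutation streams.
#' @return An `amoeba_clusters` object: `$areas` (per-area tibble with
#'   `rate`, `solution_value`, `cluster_type`, `gi_star`, `p_value`),
#'   `$ecotopes` (one row per kept ecotope), `$excluded_area_ids`, and the
#'   run parameters.
#' @export
run_amoeba <- function(areas_with_rates, adjacency, alpha = 0.01,
                       n_perm = 999L, seed = 0L) {
  stopifnot(all(c("area_id", "rate_non_act") %in% names(areas_with_rates)))
  if (alpha <= 0 || alpha >= 1) abort("alpha must lie in (0, 1)")
  if (1 / (n_perm + 1) >= alpha) {
    rlang::warn(sprintf(
      "minimum attainable p-value 1/%d is not below alpha = %g; no ecotope can be significant (increase n_perm)",
      n_perm + 1, alpha))
  }
  defined <- !is.na(areas_with_rates$rate_non_act)
  excluded <- as.character(areas_with_rates$area_id[!defined])
  df <- areas_with_rates[defined, , drop = FALSE]
  if (nrow(df) < 2L) abort("need at least 2 areas with defined rates")

  per_area <- tibble(
    area_id = as.character(df$area_id),
    rate = df$rate_non_act,
    solution_value = 0L,
    cluster_type = "outside",
    gi_star = NA_real_,
    p_value = NA_real_
  )

  constant <- stats::sd(df$rate_non_act) == 0
  if (!constant) {
    ctx <- gi_context(df$area_id, df$rate_non_act)
    # grow one candidate per seed per direction; dedupe identical regions
    seen <- new.env(parent = emptyenv())
    cands <- list()
    for (direction in c("high", "low")) {
      for (sd_id in ctx$ids) {
        reg <- grow_ecotope(sd_id, direction, ctx, adjacency)
        key <- paste(direction, paste(sort(reg), collapse = "|"))
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        cands[[length(cands) + 1L]] <- list(region = reg, direction = direction,
                                            g = gi_star(reg, ctx))
      }
    }
    # significance filter
    kept <- list()
    for (i in seq_along(cands)) {
      p <- permutation_pvalue(cands[[i]]$region, ctx, n_perm,
                              split_seed(seed, 100L + i))
      if (p < alpha) {
        cands[[i]]$p <- p
        kept[[length(kept) + 1L]] <- cands[[i]]
      }
    }
    # greedy overlap resolution by descending |G*|
    if (length(kept) > 0L) {
      ord <- order(-vapply(kept, function(cc) abs(cc$g), numeric(1)))
      taken <- character(0)
      final <- list()
      for (i in ord) {
        cc <- kept[[i]]
        if (length(intersect(cc$region, taken)) > 0L) next
        final[[length(final) + 1L]] <- cc
        taken <- c(taken, cc$region)
      }
      k_high <- 0L; k_low <- 0L
      eco_rows <- list()
      for (cc in final) {
        if (cc$direction == "high") {
          k_high <- k_high + 1L; sol <- k_high
        } else {
          k_low <- k_low + 1L; sol <- -k_low
        }
        idx <- match(cc$region, per_area$area_id)
        per_area$solution_value[idx] <- sol
        per_area$gi_star[idx] <- cc$g
        per_area$p_value[idx] <- cc$p
        eco_rows[[length(eco_rows) + 1L]] <- tibble(
          ecotope_id = sprintf("e%02d", length(eco_rows) + 1L),
          direction = cc$direction, solution_value = sol,
          n_areas = length(cc$region), gi_star = cc$g, p_value = cc$p,
          area_ids = list(sort(cc$region))
        )
      }
      ecotopes <- bind_rows(eco_rows)
    } else {
      ecotopes <- tibble(ecotope_id = character(0), direction = character(0),
                         solution_value = integer(0), n_areas = integer(0),
                         gi_star = numeric(0), p_value = numeric(0),
                         area_ids = list())
    }
  } else {
    ecotopes <- tibble(ecotope_id = character(0), direction = character(0),
                       solution_value = integer(0), n_areas = integer(0),
                       gi_star = numeric(0), p_value = numeric(0),
                       area_ids = list())
  }
  per_area$cluster_type <- classify_solution(per_area$solution_value)

  structure(list(areas = per_area, ecotopes = ecotopes,
                 excluded_area_ids = excluded,
                 alpha = alpha, n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "amoeba_clusters")
}

#' @export
print.amoeba_clusters <- function(x, ...) {
  cat("<amoeba_clusters>\n")
  cat(sprintf("  %d areas (%d with undefined rate excluded)\n",
              nrow(x$areas), length(x$excluded_area_ids)))
  nh <- sum(x$ecotopes$direction == "high")
  nl <- sum(x$ecotopes$direction == "low")
  cat(sprintf("  ecotopes kept at alpha = %g: %d high, %d low (n_perm = %d)\n",
              x$alpha, nh, nl, x$n_perm))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-area tidy view of an AMOEBA solution
#'
#' @param x An `amoeba_clusters` object.
#' @param ... Unused.
#' @return Tibble with one row per area: `area_id`, `rate`,
#'   `solution_value`, `cluster_type`, `gi_star`, `p_value`.
#' @method tidy amoeba_clusters
#' @export
tidy.amoeba_clusters <- function(x, ...) x$areas

#' One-row summary of an AMOEBA solution
#'
#' @param x An `amoeba_clusters` object.
#' @param ... Unused.
#' @return One-row tibble: areas, cluster counts, strongest |Gi*|, alpha.
#' @method glance amoeba_clusters
#' @export
glance.amoeba_clusters <- function(x, ...) {
  tibble(
    n_areas = nrow(x$areas),
    n_excluded = length(x$excluded_area_ids),
    n_high_clusters = sum(x$ecotopes$direction == "high"),
    n_low_clusters = sum(x$ecotopes$direction == "low"),
    max_abs_gi = if (nrow(x$ecotopes) > 0) max(abs(x$ecotopes$gi_star)) else NA_real_,
    alpha = x$alpha,
    n_perm = x$n_perm
  )
}
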