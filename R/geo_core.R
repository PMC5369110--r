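# Node cleaning, point-in-polygon assignment, grid selection, aggregation and
# the CCDF utility: the data-preparation layer every analysis stage sits on.

#' Remove noise nodes
#'
#' Crowdsourced intersection counts contain invalid records: nodes with an
#' all-purpose count of zero, and nodes whose commuting count exceeds the
#' all-purpose count. Both are dropped; survivor order is preserved.
#'
#' @param nodes Node tibble (see [read_nodes()]).
#' @return List with tibbles `kept` and `removed`.
#' @export
#' @examples
#' nodes <- tibble::tibble(id = c("a", "b", "c"), x = 0, y = 0,
#'                         count_total = c(5L, 0L, 2L),
#'                         count_commute = c(2L, 0L, 3L))
#' clean_nodes(nodes)$kept$id   # "a"
clean_nodes <- function(nodes) {
  stopifnot(all(c("count_total", "count_commute") %in% names(nodes)))
  bad <- nodes$count_total == 0L | nodes$count_commute > nodes$count_total
  list(kept = nodes[!bad, , drop = FALSE], removed = nodes[bad, , drop = FALSE])
}

#' Infer the non-commuting count
#'
#' The non-commuting count at a node is the difference between the
#' all-purpose count and the commuting count.
#'
#' @param nodes Cleaned node tibble.
#' @return The tibble with a `count_noncommute` integer column appended.
#' @export
infer_noncommute <- function(nodes) {
  res <- nodes$count_total - nodes$count_commute
  if (any(res < 0L)) {
    abort("count_commute exceeds count_total; run clean_nodes() first")
  }
  mutate(nodes, count_noncommute = as.integer(res))
}

#' Assign points to the polygons containing them
#'
#' Each point maps to the unique polygon whose interior contains it. Points
#' on a shared boundary map to the containing polygon with the
#' lexicographically smallest id (a deterministic, order-independent
#' tie-break); points outside every polygon map to `NA`.
#'
#' @param points Tibble with `id`, `x`, `y`.
#' @param polygons Tibble with `id` and `geometry` (list of rings).
#' @return Tibble `(point_id, polygon_id)` with `NA` polygon for unassigned
#'   points.
#' @export
assign_points_to_polygons <- function(points, polygons) {
  stopifnot(all(c("id", "x", "y") %in% names(points)),
            all(c("id", "geometry") %in% names(polygons)))
  rings <- map(polygons$geometry, as_ring)
  pids <- as.character(polygons$id)
  bb <- t(vapply(rings, function(r) c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2])),
                 numeric(4)))
  assign_one <- function(px, py) {
    cand <- which(bb[, 1] - GEOM_TOL <= px & px <= bb[, 2] + GEOM_TOL &
                    bb[, 3] - GEOM_TOL <= py & py <= bb[, 4] + GEOM_TOL)
    if (length(cand) == 0L) return(NA_character_)
    loc <- vapply(cand, function(k) point_in_polygon(px, py, rings[[k]]), character(1))
    inside <- cand[loc == "inside"]
    if (length(inside) > 1L) {
      abort(sprintf("overlapping polygon interiors: point (%g, %g) lies inside %s",
                    px, py, paste(pids[inside], collapse = " and ")))
    }
    if (length(inside) == 1L) return(pids[inside])
    bnd <- cand[loc == "boundary"]
    if (length(bnd) > 0L) return(sort(pids[bnd])[1])
    NA_character_
  }
  tibble(
    point_id = as.character(points$id),
    polygon_id = vapply(seq_len(nrow(points)),
                        function(i) assign_one(points$x[i], points$y[i]),
                        character(1))
  )
}

#' Select grid cells by the half-area rule
#'
#' Keeps cells whose intersection with the study boundary covers strictly
#' more than half of the cell's area, the standard inclusion rule for
#' background pollutant grids overlapping an administrative boundary.
#'
#' @param cells Cell tibble with `id` and square `geometry` rings.
#' @param boundary_ring Boundary polygon ring.
#' @return The subset of `cells` kept, with a `covered_fraction` column.
#' @export
select_grid_cells <- function(cells, boundary_ring) {
  boundary_ring <- as_ring(boundary_ring)
  if (polygon_area(boundary_ring) <= 0) abort("empty study boundary")
  frac <- map_dbl(cells$geometry, function(ring) {
    ring <- as_ring(ring)
    clipped <- clip_ring_rect(boundary_ring,
                              min(ring[, 1]), max(ring[, 1]),
                              min(ring[, 2]), max(ring[, 2]))
    if (nrow(clipped) < 3L) return(0)
    polygon_area(clipped) / polygon_area(ring)
  })
  out <- cells[frac > 0.5, , drop = FALSE]
  out$covered_fraction <- frac[frac > 0.5]
  out
}

#' Aggregate node counts to areal units
#'
#' Sums per-node non-commuting and commuting counts over the nodes assigned
#' to each area.
#'
#' @param nodes Cleaned node tibble with `count_noncommute` present.
#' @param assignment Tibble `(point_id, polygon_id)` from
#'   [assign_points_to_polygons()].
#' @param area_ids Character vector of all area ids (areas with no assigned
#'   node get zero counts).
#' @return Tibble `(area_id, num_non_act, num_com_act)`, one row per area.
#' @export
aggregate_to_areas <- function(nodes, assignment, area_ids) {
  stopifnot("count_noncommute" %in% names(nodes))
  joined <- nodes %>%
    inner_join(assignment, by = c(id = "point_id")) %>%
    filter(!is.na(.data$polygon_id))
  agg <- joined %>%
    group_by(area_id = .data$polygon_id) %>%
    summarise(num_non_act = sum(.data$count_noncommute),
              num_com_act = sum(.data$count_commute), .groups = "drop")
  tibble(area_id = as.character(area_ids)) %>%
    left_join(agg, by = "area_id") %>%
    mutate(num_non_act = as.integer(coalesce(.data$num_non_act, 0L)),
           num_com_act = as.integer(coalesce(.data$num_com_act, 0L)))
}

#' Empirical complementary cumulative distribution function
#'
#' `P(X > x)` evaluated at each distinct observed value: the probability that
#' the variable takes a value strictly greater than `x`. Plotted on a
#' log-linear (semi-log-y) scale, an exponential-tailed count law appears as
#' a straight line.
#'
#' @param values Non-empty numeric vector.
#' @return Tibble `(x, p)` sorted by `x`; `p` is non-increasing and
#'   `p[x == max(values)] == 0`.
#' @export
#' @examples
#' ccdf(c(1, 2, 2, 5))   # P(X > 2) = 0.25
ccdf <- function(values) {
  if (length(values) == 0L) abort("ccdf of an empty vector is undefined")
  if (!is.numeric(values)) abort("ccdf needs numeric values")
  xs <- sort(unique(values))
  n <- length(values)
  tibble(x = xs, p = vapply(xs, function(v) sum(values > v) / n, numeric(1)))
}
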