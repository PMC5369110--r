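#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort
#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map2
NULL

# Planar geometry primitives. All coordinates are projected meters; rings are
# n x 2 numeric matrices, closed or open (a repeated last vertex is dropped).

GEOM_TOL <- 1e-9

#' Normalise a polygon ring
#'
#' Coerces a ring to an open n x 2 matrix (no repeated closing vertex) and
#' validates that it has at least 3 distinct vertices.
#'
#' @param ring Numeric matrix with 2 columns (x, y), closed or open.
#' @return An open n x 2 matrix.
#' @keywords internal
as_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (!is.numeric(ring) || ncol(ring) != 2L) {
    abort("polygon ring must be a numeric matrix with columns (x, y)")
  }
  n <- nrow(ring)
  if (n >= 2L && all(abs(ring[n, ] - ring[1, ]) <= GEOM_TOL)) {
    ring <- ring[-n, , drop = FALSE]
  }
  if (nrow(ring) < 3L) abort("polygon ring needs at least 3 distinct vertices")
  ring
}

#' Signed and absolute polygon area (shoelace formula)
#'
#' @param ring Polygon ring (matrix of x, y vertices).
#' @return Absolute area in square meters.
#' @export
#' @examples
#' polygon_area(rbind(c(0, 0), c(2, 0), c(2, 1), c(0, 1)))
polygon_area <- function(ring) {
  ring <- as_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# squared distance from point p to segment a-b
.pt_seg_dist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return((px - ax)^2 + (py - ay)^2)
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- min(1, max(0, t))
  (px - (ax + t * dx))^2 + (py - (ay + t * dy))^2
}

#' Locate a point relative to a polygon
#'
#' Ray-casting with an explicit boundary test, so callers can apply
#' deterministic tie-break rules for points sitting exactly on shared edges.
#'
#' @param px,py Point coordinates.
#' @param ring Polygon ring.
#' @param tol Distance tolerance for the boundary test (meters).
#' @return One of `"inside"`, `"boundary"`, `"outside"`.
#' @export
point_in_polygon <- function(px, py, ring, tol = 1e-9) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  xs <- ring[, 1]; ys <- ring[, 2]
  nxt <- c(2:n, 1L)
  for (i in seq_len(n)) {
    if (.pt_seg_dist2(px, py, xs[i], ys[i], xs[nxt[i]], ys[nxt[i]]) <= tol^2) {
      return("boundary")
    }
  }
  # even-odd ray cast toward +x
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[nxt[i]]; y2 <- ys[nxt[i]]
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (xint > px) inside <- !inside
    }
  }
  if (inside) "inside" else "outside"
}

#' Clip a polygon by an axis-aligned rectangle (Sutherland–Hodgman)
#'
#' @param ring Subject polygon ring.
#' @param xmin,xmax,ymin,ymax Rectangle bounds.
#' @return Clipped ring matrix (possibly with 0 rows when disjoint).
#' @keywords internal
clip_ring_rect <- function(ring, xmin, xmax, ymin, ymax) {
  ring <- as_ring(ring)
  clip_half <- function(pts, keep, crossing) {
    if (nrow(pts) == 0L) return(pts)
    n <- nrow(pts)
    out <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prv <- pts[if (i == 1L) n else i - 1L, ]
      cur_in <- keep(cur); prv_in <- keep(prv)
      if (cur_in) {
        if (!prv_in) out <- rbind(out, crossing(prv, cur))
        out <- rbind(out, cur)
      } else if (prv_in) {
        out <- rbind(out, crossing(prv, cur))
      }
    }
    out
  }
  x_cross <- function(edge_x) function(p, q) {
    t <- (edge_x - p[1]) / (q[1] - p[1]); c(edge_x, p[2] + t * (q[2] - p[2]))
  }
  y_cross <- function(edge_y) function(p, q) {
    t <- (edge_y - p[2]) / (q[2] - p[2]); c(p[1] + t * (q[1] - p[1]), edge_y)
  }
  pts <- ring
  pts <- clip_half(pts, function(p) p[1] >= xmin, x_cross(xmin))
  pts <- clip_half(pts, function(p) p[1] <= xmax, x_cross(xmax))
  pts <- clip_half(pts, function(p) p[2] >= ymin, y_cross(ymin))
  pts <- clip_half(pts, function(p) p[2] <= ymax, y_cross(ymax))
  pts
}

# orientation of ordered triple: >0 counter-clockwise, <0 clockwise, 0 collinear
.orient <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

.on_seg <- function(ax, ay, bx, by, px, py, tol) {
  min(ax, bx) - tol <= px && px <= max(ax, bx) + tol &&
    min(ay, by) - tol <= py && py <= max(ay, by) + tol
}

# do closed segments a1-a2 and b1-b2 share at least one point (touching counts)?
.segments_touch <- function(a1x, a1y, a2x, a2y, b1x, b1y, b2x, b2y, tol = 1e-9) {
  d1 <- .orient(b1x, b1y, b2x, b2y, a1x, a1y)
  d2 <- .orient(b1x, b1y, b2x, b2y, a2x, a2y)
  d3 <- .orient(a1x, a1y, a2x, a2y, b1x, b1y)
  d4 <- .orient(a1x, a1y, a2x, a2y, b2x, b2y)
  if (((d1 > tol && d2 < -tol) || (d1 < -tol && d2 > tol)) &&
      ((d3 > tol && d4 < -tol) || (d3 < -tol && d4 > tol))) return(TRUE)
  if (abs(d1) <= tol && .on_seg(b1x, b1y, b2x, b2y, a1x, a1y, tol)) return(TRUE)
  if (abs(d2) <= tol && .on_seg(b1x, b1y, b2x, b2y, a2x, a2y, tol)) return(TRUE)
  if (abs(d3) <= tol && .on_seg(a1x, a1y, a2x, a2y, b1x, b1y, tol)) return(TRUE)
  if (abs(d4) <= tol && .on_seg(a1x, a1y, a2x, a2y, b2x, b2y, tol)) return(TRUE)
  FALSE
}

#' Do two polygon boundaries share at least one point? (queen contiguity test)
#'
#' @param ring_a,ring_b Polygon rings.
#' @param tol Geometric tolerance (meters).
#' @return Logical.
#' @keywords internal
rings_touch <- function(ring_a, ring_b, tol = 1e-9) {
  a <- as_ring(ring_a); b <- as_ring(ring_b)
  # bounding-box reject
  if (max(a[, 1]) + tol < min(b[, 1]) || max(b[, 1]) + tol < min(a[, 1]) ||
      max(a[, 2]) + tol < min(b[, 2]) || max(b[, 2]) + tol < min(a[, 2])) {
    return(FALSE)
  }
  na <- nrow(a); nb <- nrow(b)
  ia <- c(2:na, 1L); ib <- c(2:nb, 1L)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (.segments_touch(a[i, 1], a[i, 2], a[ia[i], 1], a[ia[i], 2],
                          b[j, 1], b[j, 2], b[ib[j], 1], b[ib[j], 2], tol)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Queen-contiguity adjacency of an areal partition
#'
#' Two areas are neighbors iff their boundaries share at least one point
#' (an edge or a single corner), the standard queen rule for irregular
#' census geographies. The relation is symmetric and irreflexive.
#'
#' @param areas Tibble with columns `id` (character) and `geometry`
#'   (list-column of polygon ring matrices).
#' @param tol Geometric tolerance in meters.
#' @return Named list: for each area id, a character vector of neighbor ids
#'   (possibly empty).
#' @export
build_adjacency <- function(areas, tol = 1e-9) {
  stopifnot(is.data.frame(areas), all(c("id", "geometry") %in% names(areas)))
  ids <- as.character(areas$id)
  if (anyDuplicated(ids)) abort("duplicate area ids")
  rings <- map(areas$geometry, as_ring)
  n <- length(rings)
  bb <- t(vapply(rings, function(r) c(min(r[, 1]), max(r[, 1]), min(r[, 2]), max(r[, 2])),
                 numeric(4)))
  nb <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) nb[[i]] <- character(0)
  if (n < 2L) return(nb)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (bb[i, 2] + tol < bb[j, 1] || bb[j, 2] + tol < bb[i, 1] ||
          bb[i, 4] + tol < bb[j, 3] || bb[j, 4] + tol < bb[i, 3]) next
      if (rings_touch(rings[[i]], rings[[j]], tol)) {
        nb[[i]] <- c(nb[[i]], ids[j])
        nb[[j]] <- c(nb[[j]], ids[i])
      }
    }
  }
  lapply(nb, sort)
}

#' Axis-aligned rectangle ring
#'
#' @param xmin,xmax,ymin,ymax Bounds in meters.
#' @return A 4 x 2 ring matrix (counter-clockwise).
#' @export
rect_ring <- function(xmin, xmax, ymin, ymax) {
  rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
}
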