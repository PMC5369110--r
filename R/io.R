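# File I/O: CSV (RFC 4180, header, UTF-8) for flat tables, GeoJSON (RFC 7946)
# for geometry layers. jsonlite handles the JSON layer; schemas are validated
# on read with errors naming the offending column/row.

NODE_COLS <- c("id", "x", "y", "count_total", "count_commute")

.is_geojson_path <- function(path) grepl("\\.(geojson|json)$", path, ignore.case = TRUE)

.check_integer_col <- function(vals, col) {
  num <- suppressWarnings(as.numeric(vals))
  bad <- which(is.na(num) | abs(num - round(num)) > 1e-9)
  if (length(bad) > 0L) {
    abort(sprintf("non-integer value in column '%s' at row %d", col, bad[1]))
  }
  as.integer(round(num))
}

#' Read a node table
#'
#' Nodes are street intersections carrying an all-purpose activity count and
#' a commuting activity count. Accepts CSV (columns
#' `id,x,y,count_total,count_commute`) or GeoJSON points with those
#' properties; both encodings yield identical tables.
#'
#' @param path Path to a `.csv` or `.geojson`/`.json` file.
#' @return Tibble with columns `id` (character), `x`, `y` (double, projected
#'   meters), `count_total`, `count_commute` (integer).
#' @export
read_nodes <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (.is_geojson_path(path)) {
    fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(fc$features)) abort("GeoJSON node file must be a FeatureCollection")
    rows <- map(fc$features, function(f) {
      props <- f$properties
      tibble(
        id = as.character(props$id %||% NA_character_),
        x = as.numeric(f$geometry$coordinates[[1]]),
        y = as.numeric(f$geometry$coordinates[[2]]),
        count_total = props$count_total %||% NA,
        count_commute = props$count_commute %||% NA
      )
    })
    df <- bind_rows(rows)
    for (col in c("id", "count_total", "count_commute")) {
      if (any(is.na(df[[col]]))) abort(sprintf("missing required property '%s'", col))
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    missing <- setdiff(NODE_COLS, names(df))
    if (length(missing) > 0L) {
      abort(sprintf("node file missing required column(s): %s",
                    paste(missing, collapse = ", ")))
    }
  }
  tibble(
    id = as.character(df$id),
    x = as.numeric(df$x),
    y = as.numeric(df$y),
    count_total = .check_integer_col(df$count_total, "count_total"),
    count_commute = .check_integer_col(df$count_commute, "count_commute")
  )
}

#' Write a node table
#'
#' @param nodes Node tibble (see [read_nodes()]).
#' @param path Output path; `.csv` writes a flat table, `.geojson` a
#'   FeatureCollection of points.
#' @return `path`, invisibly.
#' @export
write_nodes <- function(nodes, path) {
  stopifnot(all(NODE_COLS %in% names(nodes)))
  if (.is_geojson_path(path)) {
    extra <- setdiff(names(nodes), c("x", "y"))
    feats <- lapply(seq_len(nrow(nodes)), function(i) {
      props <- as.list(nodes[i, extra, drop = FALSE])
      list(
        type = "Feature",
        geometry = list(type = "Point",
                        coordinates = c(nodes$x[i], nodes$y[i])),
        properties = props
      )
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(nodes, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

.ring_to_coords <- function(ring) {
  ring <- as_ring(ring)
  closed <- rbind(ring, ring[1, ])
  lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
}

.coords_to_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  as_ring(m)
}

#' Write a polygon layer to GeoJSON
#'
#' @param df Tibble with `id`, a `geometry` list-column of rings, and any
#'   further columns written as feature properties.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(df, path) {
  stopifnot(all(c("id", "geometry") %in% names(df)))
  prop_cols <- setdiff(names(df), "geometry")
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Polygon",
                      coordinates = list(.ring_to_coords(df$geometry[[i]]))),
      properties = as.list(df[i, prop_cols, drop = FALSE])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a polygon layer from GeoJSON
#'
#' @param path `.geojson` path (FeatureCollection of Polygons).
#' @return Tibble with `id`, property columns, and a `geometry` list-column
#'   of ring matrices (exterior ring only).
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$features)) abort("expected a GeoJSON FeatureCollection")
  rows <- map(fc$features, function(f) {
    props <- f$properties
    props$id <- as.character(props$id %||% NA_character_)
    as_tibble(props)
  })
  df <- bind_rows(rows)
  df$geometry <- map(fc$features, function(f) .coords_to_ring(f$geometry$coordinates[[1]]))
  if (any(is.na(df$id))) abort("polygon feature missing 'id' property")
  df %>% relocate("id")
}

#' Write point layers (greenspace, waterbody, bus stops, city centre) to GeoJSON
#'
#' @param env EnvLayers list with tibbles `greenspace`, `waterbody`,
#'   `busstop` (columns `x`, `y`) and a length-2 `city_centre`.
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_env_layers <- function(env, path) {
  one <- function(df, layer) {
    lapply(seq_len(nrow(df)), function(i) list(
      type = "Feature",
      geometry = list(type = "Point", coordinates = c(df$x[i], df$y[i])),
      properties = list(layer = layer)
    ))
  }
  feats <- c(
    one(env$greenspace, "greenspace"),
    one(env$waterbody, "waterbody"),
    one(env$busstop, "busstop"),
    list(list(type = "Feature",
              geometry = list(type = "Point",
                              coordinates = c(env$city_centre[1], env$city_centre[2])),
              properties = list(layer = "city_centre")))
  )
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read point layers from GeoJSON
#'
#' @param path `.geojson` path written by [write_env_layers()] (points with a
#'   `layer` property among greenspace/waterbody/busstop/city_centre).
#' @return EnvLayers list (see [make_env_layers()]).
#' @export
read_env_layers <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pts <- bind_rows(map(fc$features, function(f) tibble(
    layer = as.character(f$properties$layer),
    x = as.numeric(f$geometry$coordinates[[1]]),
    y = as.numeric(f$geometry$coordinates[[2]])
  )))
  grab <- function(lay) pts %>% filter(.data$layer == lay) %>% select("x", "y")
  cc <- grab("city_centre")
  if (nrow(cc) != 1L) abort("env layer file must contain exactly one city_centre point")
  list(
    greenspace = grab("greenspace"),
    waterbody = grab("waterbody"),
    busstop = grab("busstop"),
    city_centre = c(cc$x[1], cc$y[1])
  )
}

#' Read / write a PM grid-cell table as CSV
#'
#' The flat encoding of the 1 km pollutant grid:
#' `id, centre_x, centre_y, size, pm10, pm25`.
#'
#' @param path CSV path.
#' @return Tibble of cells with a reconstructed square `geometry` list-column.
#' @export
read_pm_cells <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "centre_x", "centre_y", "size", "pm10", "pm25")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("cell file missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  df <- as_tibble(df)
  df$id <- as.character(df$id)
  df$geometry <- map2(
    seq_len(nrow(df)), df$size,
    function(i, s) rect_ring(df$centre_x[i] - s / 2, df$centre_x[i] + s / 2,
                             df$centre_y[i] - s / 2, df$centre_y[i] + s / 2)
  )
  df
}

#' @rdname read_pm_cells
#' @param cells Cell tibble with columns `id, centre_x, centre_y, size, pm10, pm25`.
#' @export
write_pm_cells <- function(cells, path) {
  need <- c("id", "centre_x", "centre_y", "size", "pm10", "pm25")
  stopifnot(all(need %in% names(cells)))
  utils::write.csv(cells[, need], path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
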