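# GeoJSON and CSV input/output. GeoJSON is read and written with jsonlite;
# the feature layer understood here is deliberately small: LineString /
# MultiLineString features carry the street segments (optional properties
# "gradient" and "passable"), Point features mark signalized nodes (optional
# "wait_override"). ESRI shapefiles are not supported: no shapefile codec is
# available to this package, and GeoJSON carries the same content.

coords_to_matrix <- function(cc) {
  do.call(rbind, lapply(cc, function(p) c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
}

#' Read a street network from a GeoJSON file
#'
#' Reads a FeatureCollection of LineString / MultiLineString features and
#' builds the noded network with [build_network()]. Point features with a
#' `signalized` property flag the nearest node (within the noding tolerance)
#' as signalized; a numeric `wait_override` property on the same point sets a
#' per-node wait. Line properties `gradient` (percent) and `passable`
#' (boolean) are carried onto edges.
#'
#' Coordinates must be projected and metric. Files written by
#' [write_network_geojson()] declare this via a `crs_units` member; for other
#' files pass `crs_units = "m"` explicitly if the extent is small enough to
#' look like degrees.
#'
#' @param path GeoJSON file
#' @param noding_tolerance merge tolerance in meters
#' @param crs_units declare `"m"` to assert metric coordinates
#' @return a `pedshed_network`
#' @export
read_network_geojson <- function(path, noding_tolerance = 0.1, crs_units = NULL) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$type) || obj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  if (identical(obj$crs_units, "m") || !is.null(obj$crs)) crs_units <- "m"
  lines <- list(); grad <- numeric(); pass <- logical()
  signals <- list()
  for (f in obj$features) {
    geom <- f$geometry
    if (is.null(geom)) next
    props <- f$properties
    g1 <- if (!is.null(props$gradient)) as.numeric(props$gradient) else NA_real_
    p1 <- if (!is.null(props$passable)) isTRUE(as.logical(props$passable)) else TRUE
    if (geom$type == "LineString") {
      lines[[length(lines) + 1L]] <- coords_to_matrix(geom$coordinates)
      grad <- c(grad, g1); pass <- c(pass, p1)
    } else if (geom$type == "MultiLineString") {
      for (part in geom$coordinates) {
        lines[[length(lines) + 1L]] <- coords_to_matrix(part)
        grad <- c(grad, g1); pass <- c(pass, p1)
      }
    } else if (geom$type == "Point") {
      signals[[length(signals) + 1L]] <- list(
        x = as.numeric(geom$coordinates[[1]]),
        y = as.numeric(geom$coordinates[[2]]),
        signalized = isTRUE(as.logical(props$signalized)),
        wait_override = if (!is.null(props$wait_override))
          as.numeric(props$wait_override) else NA_real_
      )
    }
  }
  if (length(lines) == 0) stop("no line features in ", path)
  net <- build_network(lines, noding_tolerance = noding_tolerance,
                       attributes = data.frame(gradient = grad, passable = pass),
                       crs_units = crs_units)
  for (s in signals) {
    d2 <- (net$nodes$x - s$x)^2 + (net$nodes$y - s$y)^2
    j <- which.min(d2)
    if (d2[j] <= noding_tolerance^2) {
      if (s$signalized) net$nodes$signalized[j] <- TRUE
      if (!is.na(s$wait_override)) net$nodes$wait_override[j] <- s$wait_override
    } else {
      warning(sprintf("signal point (%.1f, %.1f) matches no network node", s$x, s$y))
    }
  }
  net
}

geojson_feature <- function(geometry, properties) {
  list(type = "Feature", properties = properties, geometry = geometry)
}

write_feature_collection <- function(features, path, extra = list()) {
  obj <- c(list(type = "FeatureCollection", crs_units = "m"), extra,
           list(features = features))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = FALSE)
  invisible(path)
}

#' Write a network to GeoJSON
#'
#' Edges become LineString features (with `edge_id`, `gradient`, `passable`
#' properties); nodes carrying a signal flag or wait override become Point
#' features, so the file re-reads into an equivalent network with
#' [read_network_geojson()].
#'
#' @param network a `pedshed_network`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_network_geojson <- function(network, path) {
  stopifnot(inherits(network, "pedshed_network"))
  feats <- lapply(seq_len(nrow(network$edges)), function(i) {
    g <- network$edges$geometry[[i]]
    geojson_feature(
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(g)), function(r) c(g[r, 1], g[r, 2]))),
      list(edge_id = network$edges$id[i],
           gradient = network$edges$gradient[i],
           passable = network$edges$passable[i],
           length_m = network$edges$length[i])
    )
  })
  flagged <- which(network$nodes$signalized | !is.na(network$nodes$wait_override))
  for (i in flagged) {
    feats[[length(feats) + 1L]] <- geojson_feature(
      list(type = "Point",
           coordinates = c(network$nodes$x[i], network$nodes$y[i])),
      list(node_id = network$nodes$id[i],
           signalized = network$nodes$signalized[i],
           wait_override = network$nodes$wait_override[i])
    )
  }
  write_feature_collection(feats, path)
}

# MultiPolygon writer: assigns each hole ring to the smallest outer ring
# containing it, normalizes winding (outers counterclockwise, holes
# clockwise) per GeoJSON convention.
write_polygon_geojson <- function(rings, ring_sign, path, properties = list()) {
  if (length(rings) == 0) {
    feats <- list(geojson_feature(
      list(type = "MultiPolygon", coordinates = list()), properties))
    return(write_feature_collection(feats, path))
  }
  orient <- function(ring, ccw) {
    a <- ring_signed_area(ring)
    if ((a > 0) != ccw) ring <- ring[rev(seq_len(nrow(ring))), , drop = FALSE]
    ring
  }
  outers <- which(ring_sign > 0)
  holes <- which(ring_sign < 0)
  outer_area <- vapply(outers, function(i) abs(ring_signed_area(rings[[i]])), numeric(1))
  assignment <- lapply(seq_along(outers), function(i) integer(0))
  for (h in holes) {
    p <- rings[[h]][1, ]
    containing <- which(vapply(outers, function(o)
      point_in_ring(p[1], p[2], rings[[o]]), logical(1)))
    if (length(containing) == 0) next  # degenerate; drop the hole
    parent <- containing[which.min(outer_area[containing])]
    assignment[[parent]] <- c(assignment[[parent]], h)
  }
  close_ring <- function(ring) rbind(ring, ring[1, , drop = FALSE])
  ring_coords <- function(ring) {
    ring <- close_ring(ring)
    lapply(seq_len(nrow(ring)), function(r) c(ring[r, 1], ring[r, 2]))
  }
  polys <- lapply(seq_along(outers), function(i) {
    out <- list(ring_coords(orient(rings[[outers[i]]], ccw = TRUE)))
    for (h in assignment[[i]]) {
      out[[length(out) + 1L]] <- ring_coords(orient(rings[[h]], ccw = FALSE))
    }
    out
  })
  feats <- list(geojson_feature(list(type = "MultiPolygon", coordinates = polys),
                                properties))
  write_feature_collection(feats, path)
}

#' Read a (Multi)Polygon GeoJSON and compute its area
#'
#' Companion reader used to round-trip exported catchments: the area is the
#' sum of outer-ring shoelace areas minus hole areas.
#'
#' @param path GeoJSON file written by the package
#' @return area in m^2
#' @export
read_polygon_area_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  area <- 0
  for (f in obj$features) {
    geom <- f$geometry
    if (is.null(geom) || geom$type != "MultiPolygon") next
    for (poly in geom$coordinates) {
      for (k in seq_along(poly)) {
        ring <- coords_to_matrix(poly[[k]])
        a <- abs(ring_signed_area(ring))
        area <- area + if (k == 1) a else -a
      }
    }
  }
  area
}

#' Export agent traces
#'
#' `write_traces_geojson()` writes one Point feature per trace point with
#' `agent_id` and `t_seconds` properties — the time-filterable dataset a
#' web viewer animates. `write_traces_csv()` writes the same points as
#' `agent_id, x, y, t` rows.
#'
#' @param traces a `pedshed_traces`
#' @param path output file
#' @return invisibly, `path`
#' @export
write_traces_geojson <- function(traces, path) {
  stopifnot(inherits(traces, "pedshed_traces"))
  feats <- list()
  for (tr in traces) {
    for (r in seq_len(nrow(tr$points))) {
      feats[[length(feats) + 1L]] <- geojson_feature(
        list(type = "Point",
             coordinates = c(tr$points$x[r], tr$points$y[r])),
        list(agent_id = tr$agent_id, t_seconds = tr$points$t[r],
             completed = tr$completed)
      )
    }
  }
  write_feature_collection(feats, path)
}

#' @rdname write_traces_geojson
#' @export
write_traces_csv <- function(traces, path) {
  stopifnot(inherits(traces, "pedshed_traces"))
  rows <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(agent_id = tr$agent_id, x = tr$points$x, y = tr$points$y,
               t = tr$points$t)
  }))
  write_csv_full_precision(rows, path)
}

# CSV writer that preserves full double precision (17 significant digits) so
# written values re-read bit-identically
write_csv_full_precision <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(v) {
        if (is.na(v)) NA_character_ else sprintf("%.17g", v)
      }, character(1))
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}
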