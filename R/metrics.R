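# Walkability metrics: the buffered-network catchment polygon, the pedshed
# ratio against the equivalent circular buffer, the mean number of
# intersections crossed by agents, and scenario deltas.

# covered geometry (reached edges in full plus frontier fragments) as a
# segment table
covered_segments <- function(result) {
  edges <- result$network$edges
  cov <- result$coverage
  if (is.null(cov) || nrow(cov) == 0) {
    return(data.frame(x1 = double(), y1 = double(), x2 = double(), y2 = double()))
  }
  parts <- lapply(seq_len(nrow(cov)), function(i) {
    g <- edges$geometry[[match(cov$edge_id[i], edges$id)]]
    polyline_segments(polyline_substring(g, cov$s0[i], cov$s1[i]))
  })
  out <- do.call(rbind, parts)
  out[out$len > 0, c("x1", "y1", "x2", "y2"), drop = FALSE]
}

#' Catchment polygon of a reachability result
#'
#' The walkable catchment is operationalized as the union of all reached
#' edges and frontier fragments, each buffered by `buffer_width` on both
#' sides with round caps — the standard pedshed operationalization. The
#' polygon is extracted by contouring the exact distance-to-network field at
#' level `buffer_width` on a regular grid anchored to the network bounding
#' box (so areas from different scenarios on the same network are directly
#' comparable), and its area is the shoelace area of the resulting rings:
#' exported polygons are exactly consistent with the reported area.
#'
#' @param result a `pedshed_reachability`
#' @param buffer_width buffer half-width in meters (> 0); defaults to the
#'   configuration used for the run
#' @param resolution contour grid spacing in meters (default
#'   `buffer_width / 10`, capped at `buffer_width / 3`); smaller is more
#'   accurate and slower
#' @return a `pedshed_catchment`: list with `rings` (coordinate matrices),
#'   `ring_sign` (+1 outer boundary, -1 hole), `area` (m^2), `buffer_width`,
#'   `resolution`
#' @export
catchment_polygon <- function(result, buffer_width = result$config$buffer_width,
                              resolution = buffer_width / 10) {
  stopifnot(inherits(result, "pedshed_reachability"))
  if (buffer_width <= 0) stop("buffer_width must be > 0")
  segs <- covered_segments(result)
  net <- result$network
  bbox <- c(min(net$nodes$x), max(net$nodes$x), min(net$nodes$y), max(net$nodes$y))
  cu <- capsule_union(segs, buffer_width, resolution = resolution, bbox = bbox)
  structure(
    list(rings = cu$rings, ring_sign = cu$ring_sign, area = cu$area,
         buffer_width = buffer_width, resolution = cu$resolution),
    class = "pedshed_catchment"
  )
}

#' @export
print.pedshed_catchment <- function(x, ...) {
  cat(sprintf("<pedshed_catchment> area %.1f m^2 (%d rings, buffer %g m, grid %g m)\n",
              x$area, length(x$rings), x$buffer_width, x$resolution))
  invisible(x)
}

#' Pedshed ratio and companion catchment metrics
#'
#' Compares the buffered network catchment with the Euclidean circular buffer
#' of equivalent radius. The radius is the *gross* crow-flies range:
#' `walking_speed * max_time` for a time budget (waits do not shrink the
#' comparison circle — the circle represents the naive no-network, no-wait
#' estimate the catchment is judged against, so waits depress the ratio, not
#' the denominator) or `max_distance` for a distance budget. Dense grids
#' approach the Manhattan-diamond limit of 2/pi (~0.637); real street
#' networks score lower.
#'
#' @inheritParams catchment_polygon
#' @param traces optional `pedshed_traces` from the same run; if supplied,
#'   `mean_intersections_crossed` is filled in
#' @return a `pedshed_metrics` list: `catchment_area`, `circle_area`,
#'   `pedshed_ratio`, `reached_length`, `mean_intersections_crossed` (NA
#'   without traces), `radius_used`, `n_agents`, `config`, and the
#'   `catchment` polygon itself
#' @export
pedshed_ratio <- function(result, buffer_width = result$config$buffer_width,
                          resolution = buffer_width / 10, traces = NULL) {
  stopifnot(inherits(result, "pedshed_reachability"))
  config <- result$config
  radius <- if (config$budget_kind == "time") {
    config$walking_speed * config$max_time
  } else {
    config$max_distance
  }
  if (radius <= 0) stop("comparison circle radius is zero")
  catch <- catchment_polygon(result, buffer_width, resolution)
  circle_area <- pi * radius^2
  mic <- NA_real_
  n_agents <- NA_integer_
  if (!is.null(traces)) {
    mic <- mean_intersections_crossed(traces)
    n_agents <- length(traces)
  }
  structure(
    list(
      catchment_area = catch$area,
      circle_area = circle_area,
      pedshed_ratio = catch$area / circle_area,
      reached_length = result$reached_length,
      mean_intersections_crossed = mic,
      radius_used = radius,
      n_agents = n_agents,
      buffer_width = buffer_width,
      config = config,
      origin = result$origin,
      catchment = catch
    ),
    class = "pedshed_metrics"
  )
}

#' @export
print.pedshed_metrics <- function(x, ...) {
  cat(sprintf(
    "<pedshed_metrics> pedshed %.4f (catchment %.1f m^2 / circle %.1f m^2 at r = %g m)\n",
    x$pedshed_ratio, x$catchment_area, x$circle_area, x$radius_used
  ))
  cat(sprintf("  reached length %.1f m; mean intersections crossed %s\n",
              x$reached_length,
              if (is.na(x$mean_intersections_crossed)) "NA"
              else sprintf("%.3f", x$mean_intersections_crossed)))
  invisible(x)
}

#' Mean number of intersections crossed by the agents
#'
#' Counts, for each agent, the interior nodes of its walked path with
#' structural degree >= 3 (degree-2 vertices are geometry, not crossings;
#' origin and terminal nodes are excluded), and averages over agents.
#'
#' @param traces a `pedshed_traces` object
#' @param network the network the traces were simulated on; defaults to the
#'   one attached to `traces`
#' @return mean crossings per agent (dimensionless, >= 0)
#' @export
mean_intersections_crossed <- function(traces, network = attr(traces, "network")) {
  stopifnot(inherits(traces, "pedshed_traces"))
  if (length(traces) == 0) stop("no agent traces supplied")
  deg <- stats::setNames(node_degrees(network), network$nodes$id)
  mean(vapply(traces, function(tr) {
    if (length(tr$crossed_nodes) == 0) return(0)
    sum(deg[tr$crossed_nodes] >= 3)
  }, numeric(1)))
}

#' Compare the metrics of two scenarios
#'
#' Both runs must share the same walking parameters (speed, budget, wait,
#' scope, gradient penalty, buffer width) so that the only difference is the
#' scenario edit under test. Percent changes use the `before` scenario as
#' denominator and are undefined (NA) on a zero baseline.
#'
#' @param before,after `pedshed_metrics` objects
#' @return data.frame with columns metric, before, after, delta, pct_change
#' @export
compare_scenarios <- function(before, after) {
  stopifnot(inherits(before, "pedshed_metrics"), inherits(after, "pedshed_metrics"))
  cb <- before$config; ca <- after$config
  same <- function(a, b) isTRUE(all.equal(a, b, tolerance = 1e-12)) ||
    (is.null(a) && is.null(b))
  if (!same(cb$walking_speed, ca$walking_speed) ||
      !identical(cb$budget_kind, ca$budget_kind) ||
      !same(cb$budget, ca$budget) ||
      !same(cb$intersection_wait, ca$intersection_wait) ||
      !identical(cb$wait_scope, ca$wait_scope) ||
      !same(cb$gradient_penalty, ca$gradient_penalty) ||
      !same(before$buffer_width, after$buffer_width)) {
    stop("scenarios are not comparable: walking speed, budget, waits and ",
         "buffer width must match")
  }
  metrics <- c("catchment_area", "circle_area", "pedshed_ratio",
               "reached_length", "mean_intersections_crossed")
  b <- vapply(metrics, function(m) as.numeric(before[[m]]), numeric(1))
  a <- vapply(metrics, function(m) as.numeric(after[[m]]), numeric(1))
  delta <- a - b
  pct <- ifelse(is.na(b) | b == 0, NA_real_, 100 * delta / b)
  data.frame(metric = metrics, before = b, after = a, delta = delta,
             pct_change = pct, row.names = NULL, stringsAsFactors = FALSE)
}

#' Export metrics, catchment and circle to CSV and GeoJSON
#'
#' Writes `<prefix>_metrics.csv` (one row of scalar metrics plus the
#' configuration echo), `<prefix>_catchment.geojson` (the catchment
#' MultiPolygon, holes included) and `<prefix>_circle.geojson` (the
#' comparison circular buffer). Numbers are written at full double precision
#' so the files round-trip.
#'
#' @param metrics a `pedshed_metrics`
#' @param path_prefix path prefix for the three files
#' @param scenario_id label written into the CSV (defaults to the prefix
#'   basename)
#' @return invisibly, the named vector of file paths written
#' @export
export_metrics <- function(metrics, path_prefix,
                           scenario_id = basename(path_prefix)) {
  stopifnot(inherits(metrics, "pedshed_metrics"))
  config <- metrics$config
  row <- data.frame(
    scenario_id = scenario_id,
    walking_speed_mps = config$walking_speed,
    budget_kind = config$budget_kind,
    budget_value = config$budget,
    intersection_wait_s = config$intersection_wait,
    radius_m = metrics$radius_used,
    catchment_area_m2 = metrics$catchment_area,
    circle_area_m2 = metrics$circle_area,
    pedshed_ratio = metrics$pedshed_ratio,
    reached_length_m = metrics$reached_length,
    mean_intersections_crossed = metrics$mean_intersections_crossed,
    n_agents = metrics$n_agents,
    seed = config$seed,
    stringsAsFactors = FALSE
  )
  paths <- c(
    metrics_csv = paste0(path_prefix, "_metrics.csv"),
    catchment_geojson = paste0(path_prefix, "_catchment.geojson"),
    circle_geojson = paste0(path_prefix, "_circle.geojson")
  )
  write_csv_full_precision(row, paths["metrics_csv"])
  write_polygon_geojson(metrics$catchment$rings, metrics$catchment$ring_sign,
                        paths["catchment_geojson"],
                        properties = list(kind = "catchment",
                                          area_m2 = metrics$catchment_area))
  ring <- circle_ring(metrics$origin$point, metrics$radius_used)
  write_polygon_geojson(list(ring), 1L, paths["circle_geojson"],
                        properties = list(kind = "circular_buffer",
                                          radius_m = metrics$radius_used))
  invisible(paths)
}
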