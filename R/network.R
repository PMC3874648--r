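# Street-network model: build a noded graph from line features, snap points
# of interest onto it, apply what-if scenario edits, and validate topology.

# Cluster points within `tol` of each other; returns the index of the node
# each point maps to plus the node coordinates (first occurrence wins, so the
# result is deterministic in input order). Grid-hash so large networks stay
# near-linear.
merge_points <- function(pts, tol) {
  n <- nrow(pts)
  node_of <- integer(n)
  nx <- numeric(0); ny <- numeric(0)
  cell <- new.env(parent = emptyenv(), hash = TRUE)
  cs <- max(tol, 1e-12)
  for (i in seq_len(n)) {
    px <- pts[i, 1]; py <- pts[i, 2]
    cx <- floor(px / cs); cy <- floor(py / cs)
    found <- 0L
    for (ox in -1:1) {
      for (oy in -1:1) {
        key <- paste(cx + ox, cy + oy, sep = "|")
        ids <- cell[[key]]
        if (!is.null(ids)) {
          d2 <- (nx[ids] - px)^2 + (ny[ids] - py)^2
          hit <- ids[d2 <= tol^2]
          if (length(hit)) { found <- hit[1]; break }
        }
      }
      if (found) break
    }
    if (!found) {
      nx <- c(nx, px); ny <- c(ny, py)
      found <- length(nx)
      key <- paste(cx, cy, sep = "|")
      cell[[key]] <- c(cell[[key]], found)
    }
    node_of[i] <- found
  }
  list(node_of = node_of, x = nx, y = ny)
}

new_network <- function(nodes, edges, noding_tolerance) {
  structure(
    list(nodes = nodes, edges = edges, noding_tolerance = noding_tolerance,
         crs_units = "m"),
    class = "pedshed_network"
  )
}

#' Build a noded street network from line features
#'
#' Splits the input polylines at every mutual crossing and endpoint contact
#' ("noding"), merges coincident endpoints within `noding_tolerance` into
#' shared intersection nodes, and returns an undirected network graph whose
#' edges keep their full polyline geometry. Degree-2 vertices interior to a
#' polyline remain geometry, not nodes. Zero-length pieces left over after
#' tolerance merging are collapsed into their node.
#'
#' Coordinates must be planar and metric (a projected CRS). If every
#' coordinate falls inside the longitude/latitude range and the units were
#' not declared metric, the input is assumed geographic and rejected.
#'
#' @param lines list of two-column coordinate matrices (one polyline each)
#' @param noding_tolerance merge tolerance in meters (default 0.1, typical
#'   road-centerline digitizing precision)
#' @param attributes optional data.frame with one row per line; recognised
#'   columns: `gradient` (percent slope, >= 0), `passable` (logical)
#' @param crs_units declare `"m"` to assert the coordinates are metric
#' @return an object of class `pedshed_network` with `$nodes`
#'   (id, x, y, signalized, wait_override) and `$edges`
#'   (id, from, to, length, gradient, passable, geometry list-column)
#' @examples
#' net <- build_network(
#'   list(cbind(c(0, 200), c(100, 100)), cbind(c(100, 100), c(0, 200))),
#'   crs_units = "m"
#' )
#' nrow(net$nodes) # 5: one new node at the crossing
#' @export
build_network <- function(lines, noding_tolerance = 0.1, attributes = NULL,
                          crs_units = NULL) {
  if (length(lines) == 0) stop("no line features supplied")
  lines <- lapply(lines, clean_polyline)
  keep <- vapply(lines, function(l) nrow(l) >= 2, logical(1))
  if (!is.null(attributes)) attributes <- attributes[keep, , drop = FALSE]
  lines <- lines[keep]
  if (length(lines) == 0) stop("no line features with positive length")

  allc <- do.call(rbind, lines)
  if (!identical(crs_units, "m") &&
      all(abs(allc[, 1]) <= 180) && all(abs(allc[, 2]) <= 90)) {
    stop("coordinates look geographic (degrees); reproject to a projected ",
         "metric CRS, or pass crs_units = \"m\" if they really are meters")
  }

  grad <- rep(NA_real_, length(lines))
  pass <- rep(TRUE, length(lines))
  if (!is.null(attributes)) {
    if (!is.null(attributes$gradient)) grad <- as.numeric(attributes$gradient)
    if (!is.null(attributes$passable)) {
      p <- attributes$passable
      pass <- ifelse(is.na(p), TRUE, as.logical(p))
    }
  }
  if (any(!is.na(grad) & grad < 0)) stop("gradient must be >= 0 (percent)")

  nl <- length(lines)
  segtabs <- lapply(lines, polyline_segments)
  lens <- vapply(lines, polyline_length, numeric(1))
  splits <- lapply(lens, function(L) c(0, L))

  # pass 1: proper crossings between distinct polylines
  if (nl > 1) {
    for (i in seq_len(nl - 1)) {
      si <- segtabs[[i]]
      others <- (i + 1):nl
      sj <- do.call(rbind, segtabs[others])
      owner <- rep(others, vapply(segtabs[others], nrow, integer(1)))
      if (nrow(sj) == 0) next
      for (k in seq_len(nrow(si))) {
        hits <- segment_intersections(si$x1[k], si$y1[k], si$x2[k], si$y2[k],
                                      sj$x1, sj$y1, sj$x2, sj$y2)
        if (nrow(hits) == 0) next
        splits[[i]] <- c(splits[[i]], si$s0[k] + hits$t * si$len[k])
        for (r in seq_len(nrow(hits))) {
          j <- owner[hits$i[r]]
          splits[[j]] <- c(splits[[j]],
                           sj$s0[hits$i[r]] + hits$u[r] * sj$len[hits$i[r]])
        }
      }
    }
  }

  # pass 2: endpoint-to-other-line contacts within tolerance (T junctions
  # with digitizing slop that the exact crossing test cannot see)
  ends <- do.call(rbind, lapply(seq_len(nl), function(i) {
    l <- lines[[i]]
    cbind(i, rbind(l[1, ], l[nrow(l), ]))
  }))
  for (r in seq_len(nrow(ends))) {
    i <- ends[r, 1]; px <- ends[r, 2]; py <- ends[r, 3]
    for (j in seq_len(nl)) {
      if (j == i) next
      sj <- segtabs[[j]]
      pr <- point_segment_projection(px, py, sj$x1, sj$y1, sj$x2, sj$y2)
      b <- which.min(pr$dist2)
      if (length(b) && pr$dist2[b] <= noding_tolerance^2) {
        splits[[j]] <- c(splits[[j]], sj$s0[b] + pr$t[b] * sj$len[b])
      }
    }
  }

  # cut each polyline at its split offsets
  pieces <- list(); piece_line <- integer()
  for (i in seq_len(nl)) {
    s <- sort(unique(pmin(pmax(splits[[i]], 0), lens[i])))
    # drop split positions closer than the tolerance to each other
    if (length(s) > 1) s <- s[c(TRUE, diff(s) > noding_tolerance / 2)]
    if (s[length(s)] < lens[i]) s <- c(s, lens[i])
    if (length(s) < 2) next
    for (k in seq_len(length(s) - 1)) {
      pieces[[length(pieces) + 1L]] <- polyline_substring(lines[[i]], s[k], s[k + 1])
      piece_line <- c(piece_line, i)
    }
  }

  # merge piece endpoints into nodes
  endpts <- do.call(rbind, lapply(pieces, function(p) rbind(p[1, ], p[nrow(p), ])))
  mg <- merge_points(endpts, noding_tolerance)
  from <- mg$node_of[seq(1, length(mg$node_of), by = 2)]
  to <- mg$node_of[seq(2, length(mg$node_of), by = 2)]

  # snap piece endpoints onto the merged node coordinates and collapse
  # zero-length leftovers
  geoms <- list(); e_from <- integer(); e_to <- integer()
  e_len <- numeric(); e_grad <- numeric(); e_pass <- logical()
  for (k in seq_along(pieces)) {
    g <- pieces[[k]]
    g[1, ] <- c(mg$x[from[k]], mg$y[from[k]])
    g[nrow(g), ] <- c(mg$x[to[k]], mg$y[to[k]])
    g <- clean_polyline(g)
    L <- polyline_length(g)
    if (from[k] == to[k] && L <= noding_tolerance) next  # collapsed
    if (nrow(g) < 2) next
    geoms[[length(geoms) + 1L]] <- g
    e_from <- c(e_from, from[k]); e_to <- c(e_to, to[k])
    e_len <- c(e_len, L)
    e_grad <- c(e_grad, grad[piece_line[k]])
    e_pass <- c(e_pass, pass[piece_line[k]])
  }
  if (length(geoms) == 0) stop("noding left no usable edges")

  used <- sort(unique(c(e_from, e_to)))
  remap <- integer(length(mg$x)); remap[used] <- seq_along(used)
  nodes <- data.frame(
    id = sprintf("n%d", seq_along(used)),
    x = mg$x[used], y = mg$y[used],
    signalized = FALSE, wait_override = NA_real_,
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    id = sprintf("e%d", seq_along(geoms)),
    from = sprintf("n%d", remap[e_from]),
    to = sprintf("n%d", remap[e_to]),
    length = e_len, gradient = e_grad, passable = e_pass,
    stringsAsFactors = FALSE
  )
  edges$geometry <- geoms
  new_network(nodes, edges, noding_tolerance)
}

#' @export
print.pedshed_network <- function(x, ...) {
  cat(sprintf(
    "<pedshed_network> %d nodes, %d edges, total length %.1f m (tolerance %g m)\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$length), x$noding_tolerance
  ))
  if (any(x$nodes$signalized)) {
    cat(sprintf("  signalized nodes: %d\n", sum(x$nodes$signalized)))
  }
  if (any(!x$edges$passable)) {
    cat(sprintf("  impassable edges: %d\n", sum(!x$edges$passable)))
  }
  invisible(x)
}

# One row per constituent segment across all edge geometries, tagged with
# edge index and offset along the edge.
network_segment_table <- function(network, edge_ids = NULL) {
  edges <- network$edges
  if (!is.null(edge_ids)) edges <- edges[edges$id %in% edge_ids, , drop = FALSE]
  if (nrow(edges) == 0) {
    return(data.frame(edge = character(), x1 = double(), y1 = double(),
                      x2 = double(), y2 = double(), s0 = double(),
                      len = double()))
  }
  tabs <- lapply(seq_len(nrow(edges)), function(i) {
    st <- polyline_segments(edges$geometry[[i]])
    if (nrow(st)) st$edge <- edges$id[i]
    st
  })
  do.call(rbind, tabs[vapply(tabs, nrow, integer(1)) > 0])
}

#' Snap a point onto the nearest network edge
#'
#' Projects an off-network point (an origin or destination of interest) onto
#' the closest location on any edge. Ties are broken deterministically by
#' lowest edge id, then lowest offset.
#'
#' @param network a `pedshed_network`
#' @param point numeric vector c(x, y) in meters
#' @param max_snap_distance error if the nearest edge is farther than this
#' @return a `pedshed_location`: list with `edge_id`, `offset` (meters from
#'   the edge's first endpoint), `point` (snapped coordinates) and
#'   `snap_distance`
#' @export
snap_point <- function(network, point, max_snap_distance = Inf) {
  stopifnot(inherits(network, "pedshed_network"))
  if (nrow(network$edges) == 0) stop("network has no edges")
  point <- as.numeric(point)
  st <- network_segment_table(network)
  pr <- point_segment_projection(point[1], point[2], st$x1, st$y1, st$x2, st$y2)
  d <- sqrt(pr$dist2)
  dmin <- min(d)
  if (dmin > max_snap_distance) {
    stop(sprintf("nearest network edge is %.3f m away (max_snap_distance = %g m)",
                 dmin, max_snap_distance))
  }
  cand <- which(d <= dmin + 1e-9)
  off <- st$s0[cand] + pr$t[cand] * st$len[cand]
  eidx <- match(st$edge[cand], network$edges$id)
  ord <- order(eidx, off)
  b <- cand[ord[1]]
  edge_id <- st$edge[b]
  offset <- min(max(st$s0[b] + pr$t[b] * st$len[b], 0),
                network$edges$length[match(edge_id, network$edges$id)])
  structure(
    list(edge_id = edge_id, offset = offset,
         point = c(pr$qx[b], pr$qy[b]), snap_distance = d[b]),
    class = "pedshed_location"
  )
}

#' @export
print.pedshed_location <- function(x, ...) {
  cat(sprintf("<pedshed_location> edge %s @ %.2f m (snap distance %.2f m)\n",
              x$edge_id, x$offset, x$snap_distance))
  invisible(x)
}

#' Scenario edits
#'
#' Constructors for the what-if edits understood by [apply_edit()]: add a new
#' street segment (re-noded against the network), remove one, toggle a
#' signal, or move the origin of interest.
#'
#' @param geometry two-column coordinate matrix of the new line
#' @param gradient optional percent slope for the new line
#' @param passable logical, whether the new line can be walked
#' @param edge_id,node_id ids in the network being edited
#' @param x,y origin coordinates
#' @return a `pedshed_edit` object
#' @name scenario_edit
NULL

#' @rdname scenario_edit
#' @export
edit_add_edge <- function(geometry, gradient = NA_real_, passable = TRUE) {
  structure(list(kind = "add_edge", geometry = clean_polyline(geometry),
                 gradient = gradient, passable = passable),
            class = "pedshed_edit")
}

#' @rdname scenario_edit
#' @export
edit_remove_edge <- function(edge_id) {
  structure(list(kind = "remove_edge", edge_id = edge_id), class = "pedshed_edit")
}

#' @rdname scenario_edit
#' @export
edit_toggle_signal <- function(node_id) {
  structure(list(kind = "toggle_signal", node_id = node_id), class = "pedshed_edit")
}

#' @rdname scenario_edit
#' @export
edit_set_origin <- function(x, y) {
  structure(list(kind = "set_origin", point = c(x, y)), class = "pedshed_edit")
}

#' Apply a scenario edit to a network
#'
#' Returns a new network; the input is never modified. Adding an edge
#' re-nodes the new line against the existing network, so new crossings
#' become intersection nodes. Removing an edge also drops nodes left without
#' any incident edge. Node attributes (signals, wait overrides) survive
#' re-noding by coordinate matching within the noding tolerance.
#'
#' @param network a `pedshed_network`
#' @param edit a `pedshed_edit` from [edit_add_edge()] and friends
#' @return the edited `pedshed_network`
#' @export
apply_edit <- function(network, edit) {
  stopifnot(inherits(network, "pedshed_network"), inherits(edit, "pedshed_edit"))
  if (edit$kind == "remove_edge") {
    i <- match(edit$edge_id, network$edges$id)
    if (is.na(i)) stop(sprintf("cannot remove edge '%s': no such edge id", edit$edge_id))
    network$edges <- network$edges[-i, , drop = FALSE]
    used <- unique(c(network$edges$from, network$edges$to))
    network$nodes <- network$nodes[network$nodes$id %in% used, , drop = FALSE]
    rownames(network$edges) <- rownames(network$nodes) <- NULL
    return(network)
  }
  if (edit$kind == "toggle_signal") {
    i <- match(edit$node_id, network$nodes$id)
    if (is.na(i)) stop(sprintf("cannot toggle signal at '%s': no such node id", edit$node_id))
    network$nodes$signalized[i] <- !network$nodes$signalized[i]
    return(network)
  }
  if (edit$kind == "set_origin") {
    network$origin <- edit$point
    return(network)
  }
  if (edit$kind == "add_edge") {
    geoms <- c(network$edges$geometry, list(edit$geometry))
    attrs <- data.frame(
      gradient = c(network$edges$gradient, edit$gradient),
      passable = c(network$edges$passable, isTRUE(edit$passable))
    )
    out <- build_network(geoms, noding_tolerance = network$noding_tolerance,
                         attributes = attrs, crs_units = "m")
    # carry node attributes across the rebuild by position
    flagged <- network$nodes[network$nodes$signalized |
                               !is.na(network$nodes$wait_override), , drop = FALSE]
    if (nrow(flagged)) {
      for (r in seq_len(nrow(flagged))) {
        d2 <- (out$nodes$x - flagged$x[r])^2 + (out$nodes$y - flagged$y[r])^2
        j <- which.min(d2)
        if (d2[j] <= network$noding_tolerance^2) {
          out$nodes$signalized[j] <- flagged$signalized[r]
          out$nodes$wait_override[j] <- flagged$wait_override[r]
        }
      }
    }
    out$origin <- network$origin
    return(out)
  }
  stop(sprintf("unknown edit kind '%s'", edit$kind))
}

# structural degree of every node (impassable edges still count: a barrier
# crossing is still an intersection)
node_degrees <- function(network) {
  deg <- table(factor(c(network$edges$from, network$edges$to),
                      levels = network$nodes$id))
  as.integer(deg)
}

#' Validate a network and report its topology
#'
#' @param network a `pedshed_network`
#' @return list with node/edge counts, connected component count and sizes,
#'   dangling (degree-1) node ids, isolated node ids, any zero-length edge
#'   ids (flagged, never dropped), and total edge length
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "pedshed_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to")], directed = FALSE,
    vertices = network$nodes$id
  )
  comp <- igraph::components(g)
  deg <- node_degrees(network)
  zl <- network$edges$id[network$edges$length <= max(network$noding_tolerance, 1e-9)]
  structure(
    list(
      n_nodes = nrow(network$nodes),
      n_edges = nrow(network$edges),
      n_components = comp$no,
      component_sizes = as.integer(comp$csize),
      dangling_nodes = network$nodes$id[deg == 1],
      isolated_nodes = network$nodes$id[deg == 0],
      zero_length_edges = zl,
      total_length = sum(network$edges$length)
    ),
    class = "pedshed_validation"
  )
}

#' @export
print.pedshed_validation <- function(x, ...) {
  cat(sprintf("<pedshed_validation> %d nodes / %d edges, %d component(s), total %.1f m\n",
              x$n_nodes, x$n_edges, x$n_components, x$total_length))
  cat(sprintf("  dangling nodes: %d, isolated nodes: %d, zero-length edges: %d\n",
              length(x$dangling_nodes), length(x$isolated_nodes),
              length(x$zero_length_edges)))
  invisible(x)
}
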