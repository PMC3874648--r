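# Synthetic street networks: parameterized fixtures (grids, a single road,
# a cul-de-sac suburb with a proposed connector, river barriers) so every
# pipeline stage can be exercised with no external data. Fixtures are
# geometry-first — real coordinates run through the same noding, snapping and
# buffering code as user data.

#' Orthogonal grid street network
#'
#' `rows x cols` intersection nodes spaced `spacing` meters apart, built by
#' noding full-length row/column polylines (so the generator exercises the
#' same code path as imported data). The result has `rows*cols` nodes and
#' `rows*(cols-1) + cols*(rows-1)` edges of uniform length.
#'
#' @param rows,cols integers >= 2
#' @param spacing edge length in meters
#' @param signal_fraction fraction of degree->=3 nodes flagged as signalized,
#'   assigned reproducibly from `seed`
#' @param seed integer seed for the signal assignment
#' @param origin lower-left corner coordinates
#' @return a `pedshed_network`
#' @export
make_grid <- function(rows, cols, spacing = 100, signal_fraction = 0,
                      seed = 1L, origin = c(0, 0)) {
  stopifnot(rows >= 2, cols >= 2, spacing > 0,
            signal_fraction >= 0, signal_fraction <= 1)
  xs <- origin[1] + (seq_len(cols) - 1) * spacing
  ys <- origin[2] + (seq_len(rows) - 1) * spacing
  lines <- c(
    lapply(ys, function(y) cbind(range(xs), c(y, y))),
    lapply(xs, function(x) cbind(c(x, x), range(ys)))
  )
  net <- build_network(lines, noding_tolerance = min(0.1, spacing / 1000),
                       crs_units = "m")
  if (signal_fraction > 0) {
    deg <- node_degrees(net)
    eligible <- which(deg >= 3)
    k <- round(signal_fraction * length(eligible))
    if (k > 0) {
      pick <- with_local_seed(seed, sample(eligible, k))
      net$nodes$signalized[pick] <- TRUE
    }
  }
  net
}

#' Single straight road
#'
#' One edge of the given length along the x axis — the analytic test case:
#' reachability from the midpoint gives r = v*t in each direction and a
#' closed-form capsule catchment.
#'
#' @param length road length in meters
#' @return a `pedshed_network` with 2 nodes and 1 edge
#' @export
make_single_road <- function(length = 3000) {
  stopifnot(length > 0)
  build_network(list(cbind(c(0, length), c(0, 0))), crs_units = "m")
}

#' Cul-de-sac suburb with a proposed connector
#'
#' A low-connectivity comb layout: a spine road with dead-end branches of
#' seeded, slightly varying length. The returned `edit` adds a connector
#' between two adjacent branch tips — the classic walkability retrofit —
#' which strictly increases the catchment from the suggested origin at the
#' end of the spine.
#'
#' @param seed integer; jitters branch lengths reproducibly
#' @return list with `network`, `edit` (an add-edge `pedshed_edit`),
#'   and `origin` coordinates
#' @export
make_culdesac_suburb <- function(seed = 1L) {
  branch_x <- seq(0, 400, by = 100)
  branch_len <- with_local_seed(seed, stats::runif(length(branch_x), 180, 220))
  lines <- c(
    list(cbind(c(0, 400), c(0, 0))),  # spine
    lapply(seq_along(branch_x), function(i) {
      cbind(c(branch_x[i], branch_x[i]), c(0, branch_len[i]))
    })
  )
  net <- build_network(lines, crs_units = "m")
  # connector between the tips of branches 3 and 4 (x = 200 and x = 300):
  # adjacent tips, so the new line crosses nothing in between
  connector <- cbind(c(200, 300), c(branch_len[3], branch_len[4]))
  list(
    network = net,
    edit = edit_add_edge(connector),
    origin = c(0, 0)
  )
}

#' Cut a river barrier through a network
#'
#' Marks every edge crossing the given axis line as impassable, except
#' `n_crossings` kept passable as bridges. Bridges are chosen reproducibly:
#' the crossings closest to the middle of the barrier line first (ties by
#' edge id).
#'
#' @param network a `pedshed_network`
#' @param axis `"v"` for a vertical barrier (x = position) or `"h"` for a
#'   horizontal one (y = position)
#' @param position barrier coordinate in meters
#' @param n_crossings number of crossings left passable (0 to all available)
#' @return the modified `pedshed_network`
#' @export
add_river_barrier <- function(network, axis = c("v", "h"), position,
                              n_crossings = 1L) {
  stopifnot(inherits(network, "pedshed_network"))
  axis <- match.arg(axis)
  coord_col <- if (axis == "v") 1 else 2
  other_col <- if (axis == "v") 2 else 1
  crossing <- vapply(network$edges$geometry, function(g) {
    v <- g[, coord_col] - position
    any(v[-1] * v[-length(v)] < 0)
  }, logical(1))
  idx <- which(crossing)
  if (n_crossings < 0 || n_crossings > length(idx)) {
    stop(sprintf("n_crossings must be between 0 and %d (crossings available)",
                 length(idx)))
  }
  if (length(idx)) {
    mid <- vapply(idx, function(i) {
      g <- network$edges$geometry[[i]]
      mean(range(g[, other_col]))
    }, numeric(1))
    center <- mean(range(mid))
    keep <- idx[order(abs(mid - center), match(network$edges$id[idx],
                                               network$edges$id))][seq_len(n_crossings)]
    network$edges$passable[setdiff(idx, keep)] <- FALSE
  }
  network
}
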