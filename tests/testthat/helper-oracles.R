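# Independent oracles used by the tests. These deliberately avoid the
# package's own graph/geometry code paths: Bellman-Ford relaxation for
# arrivals, brute-force pairwise intersection counting for noding, dense
# sampling for snapping, and flood fill for components.

# Bellman-Ford (relax-to-fixpoint) arrival times with the composite cost:
# gradient-adjusted traversal time plus waits at interior nodes (time mode)
# or plain length (distance mode). Origin may lie mid-edge.
oracle_arrivals <- function(network, origin, config) {
  edges <- network$edges[network$edges$passable, , drop = FALSE]
  time_mode <- config$budget_kind == "time"
  grad <- ifelse(is.na(edges$gradient), 0, edges$gradient)
  sp <- config$walking_speed * pmax(0.2, 1 - config$gradient_penalty * grad)
  cost <- if (time_mode) edges$length / sp else edges$length

  deg <- as.integer(table(factor(c(network$edges$from, network$edges$to),
                                 levels = network$nodes$id)))
  w <- ifelse(network$nodes$signalized |
                (config$wait_scope == "all_intersections" & deg >= 3),
              config$intersection_wait, 0)
  w <- ifelse(!is.na(network$nodes$wait_override),
              network$nodes$wait_override, w)
  names(w) <- network$nodes$id
  if (!time_mode) w[] <- 0
  w <- c(w, ".o" = 0)

  tails <- c(edges$from, edges$to)
  heads <- c(edges$to, edges$from)
  cc <- c(cost, cost)

  ei <- match(origin$edge_id, edges$id)
  stopifnot(!is.na(ei))
  o <- origin$offset
  L <- edges$length[ei]
  if (o > 1e-9 && o < L - 1e-9) {
    drop <- c(ei, ei + nrow(edges))
    tails <- tails[-drop]; heads <- heads[-drop]; cc <- cc[-drop]
    c1 <- cost[ei] * o / L
    c2 <- cost[ei] * (L - o) / L
    tails <- c(tails, edges$from[ei], ".o", ".o", edges$to[ei])
    heads <- c(heads, ".o", edges$from[ei], edges$to[ei], ".o")
    cc <- c(cc, c1, c1, c2, c2)
    src <- ".o"
  } else {
    src <- if (o <= 1e-9) edges$from[ei] else edges$to[ei]
  }

  ids <- unique(c(network$nodes$id, src))
  arr <- stats::setNames(rep(Inf, length(ids)), ids)
  arr[src] <- 0
  repeat {
    cand <- arr[tails] + ifelse(tails == src, 0, w[tails]) + cc
    new <- tapply(cand, heads, min)
    cur <- arr[names(new)]
    upd <- pmin(cur, new)
    gap <- cur - upd
    gap[is.nan(gap)] <- 0
    if (all(gap < 1e-12)) break
    arr[names(new)] <- upd
  }
  arr[intersect(names(arr), network$nodes$id)]
}

# brute-force all-pairs segment-intersection oracle: expected node and edge
# counts after noding a set of single-segment lines (generic positions, so
# the tolerance only merges exactly coincident points)
oracle_noding_counts <- function(lines, tol) {
  n <- length(lines)
  splits <- replicate(n, c(0, 1), simplify = FALSE)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        p <- lines[[i]]; q <- lines[[j]]
        r <- p[2, ] - p[1, ]; s <- q[2, ] - q[1, ]
        den <- r[1] * s[2] - r[2] * s[1]
        if (abs(den) < 1e-12) next
        t <- ((q[1, 1] - p[1, 1]) * s[2] - (q[1, 2] - p[1, 2]) * s[1]) / den
        u <- ((q[1, 1] - p[1, 1]) * r[2] - (q[1, 2] - p[1, 2]) * r[1]) / den
        if (t >= -1e-9 && t <= 1 + 1e-9 && u >= -1e-9 && u <= 1 + 1e-9) {
          splits[[i]] <- c(splits[[i]], t)
          splits[[j]] <- c(splits[[j]], u)
        }
      }
    }
  }
  edge_count <- 0
  pts <- NULL
  for (i in seq_len(n)) {
    p <- lines[[i]]
    L <- sqrt(sum((p[2, ] - p[1, ])^2))
    s <- sort(unique(pmin(pmax(splits[[i]], 0), 1)))
    s <- s[c(TRUE, diff(s) * L > tol / 2)]
    if (s[length(s)] < 1) s <- c(s, 1)
    edge_count <- edge_count + length(s) - 1
    pts <- rbind(pts, cbind(p[1, 1] + s * (p[2, 1] - p[1, 1]),
                            p[1, 2] + s * (p[2, 2] - p[1, 2])))
  }
  # greedy clustering of split points within the tolerance
  node_count <- 0
  taken <- rep(FALSE, nrow(pts))
  for (k in seq_len(nrow(pts))) {
    if (taken[k]) next
    node_count <- node_count + 1
    d2 <- (pts[, 1] - pts[k, 1])^2 + (pts[, 2] - pts[k, 2])^2
    taken[d2 <= tol^2] <- TRUE
  }
  list(nodes = node_count, edges = edge_count)
}

# dense-sampling snap oracle: nearest location among points sampled every
# `step` meters along every edge
oracle_snap <- function(network, point, step = 0.01) {
  best <- list(dist = Inf)
  for (i in seq_len(nrow(network$edges))) {
    g <- network$edges$geometry[[i]]
    L <- network$edges$length[i]
    s <- unique(c(seq(0, L, by = step), L))
    cum <- c(0, cumsum(sqrt(diff(g[, 1])^2 + diff(g[, 2])^2)))
    seg <- pmin(pmax(findInterval(s, cum, rightmost.closed = TRUE), 1), nrow(g) - 1)
    den <- cum[seg + 1] - cum[seg]
    t <- ifelse(den > 0, (s - cum[seg]) / den, 0)
    px <- g[seg, 1] + t * (g[seg + 1, 1] - g[seg, 1])
    py <- g[seg, 2] + t * (g[seg + 1, 2] - g[seg, 2])
    d <- sqrt((px - point[1])^2 + (py - point[2])^2)
    k <- which.min(d)
    if (d[k] < best$dist) {
      best <- list(dist = d[k], edge_id = network$edges$id[i], offset = s[k])
    }
  }
  best
}

# BFS flood-fill component count
oracle_components <- function(network) {
  ids <- network$nodes$id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_len(nrow(network$edges))) {
    f <- network$edges$from[k]; t <- network$edges$to[k]
    adj[[f]] <- c(adj[[f]], t)
    adj[[t]] <- c(adj[[t]], f)
  }
  seen <- stats::setNames(rep(FALSE, length(ids)), ids)
  ncomp <- 0
  for (id in ids) {
    if (seen[id]) next
    ncomp <- ncomp + 1
    queue <- id
    seen[id] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[!seen[nb]]
      seen[new] <- TRUE
      queue <- c(queue, new)
    }
  }
  ncomp
}

# random single-segment network in a box, generic positions
random_segment_lines <- function(n_segments, extent = 500) {
  lapply(seq_len(n_segments), function(i) {
    matrix(stats::runif(4, 0, extent), 2, 2)
  })
}

random_test_network <- function(n_segments = 12, extent = 500,
                                with_attrs = TRUE, tol = 1e-6) {
  lines <- random_segment_lines(n_segments, extent)
  attrs <- NULL
  if (with_attrs) {
    attrs <- data.frame(
      gradient = ifelse(stats::runif(n_segments) < 0.3,
                        stats::runif(n_segments, 0, 12), NA_real_),
      passable = stats::runif(n_segments) > 0.05
    )
    if (!any(attrs$passable)) attrs$passable[1] <- TRUE
  }
  net <- build_network(lines, noding_tolerance = tol, attributes = attrs,
                       crs_units = "m")
  # sprinkle signals and overrides
  if (with_attrs && nrow(net$nodes) > 2) {
    k <- sample(nrow(net$nodes), max(1, nrow(net$nodes) %/% 4))
    net$nodes$signalized[k] <- TRUE
    k2 <- sample(nrow(net$nodes), 1)
    net$nodes$wait_override[k2] <- stats::runif(1, 0, 45)
  }
  net
}

random_test_config <- function() {
  time_mode <- stats::runif(1) < 0.7
  simulation_config(
    walking_speed = stats::runif(1, 0.5, 2),
    max_time = if (time_mode) stats::runif(1, 120, 1200) else NULL,
    max_distance = if (!time_mode) stats::runif(1, 100, 2000) else NULL,
    intersection_wait = sample(c(0, 10, 30, 60), 1),
    wait_scope = sample(c("signalized_only", "all_intersections"), 1),
    gradient_penalty = sample(c(0, 0.05, 0.1), 1),
    n_destinations = 5,
    seed = sample.int(1e6, 1)
  )
}

# a location guaranteed to sit on a passable edge
random_origin <- function(net) {
  passable <- which(net$edges$passable)
  ei <- sample(passable, 1)
  off <- stats::runif(1) * net$edges$length[ei]
  pt <- pedshed:::polyline_point_at(net$edges$geometry[[ei]], off)
  structure(list(edge_id = net$edges$id[ei], offset = off, point = pt,
                 snap_distance = 0), class = "pedshed_location")
}
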