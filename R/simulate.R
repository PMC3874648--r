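# The agent model: effective walking speed on gradients, intersection waits,
# time/distance-budgeted reachability (earliest arrivals, reached edges,
# frontier fragments), random destination sampling, and A-Star-routed agents
# rendered as equally spaced time-stamped traces.
#
# Reachability is computed once by shortest-path expansion over the noded
# graph rather than by literally stepping thousands of agents; the agent
# traces are a view over the optimal paths, which gives identical results at
# desk-scale cost.

# effective speed per edge: a linear slowdown per percent slope, floored at
# 20% of the flat-ground speed; edges without a gradient walk at full speed
effective_speed <- function(gradient, config) {
  g <- ifelse(is.na(gradient), 0, gradient)
  config$walking_speed * pmax(0.2, 1 - config$gradient_penalty * g)
}

#' Time to traverse an edge
#'
#' @param edge a one-row slice of `network$edges` (or a list with `length`,
#'   `gradient`, `passable`)
#' @param config a `pedshed_config`
#' @return traversal time in seconds at the gradient-adjusted walking speed
#' @export
edge_traversal_time <- function(edge, config) {
  stopifnot(inherits(config, "pedshed_config"))
  passable <- if (is.null(edge$passable)) TRUE else isTRUE(all(edge$passable))
  if (!passable) stop("edge is impassable")
  as.numeric(edge$length) / effective_speed(as.numeric(edge$gradient), config)
}

# waits charged when an agent passes *through* each node (interior to its
# path); origin and the final stop never wait, which callers implement by
# not charging the first/last path node
node_wait_vector <- function(network, config) {
  deg <- node_degrees(network)
  w <- ifelse(
    network$nodes$signalized |
      (config$wait_scope == "all_intersections" & deg >= 3),
    config$intersection_wait, 0
  )
  ov <- network$nodes$wait_override
  w <- ifelse(!is.na(ov), ov, w)
  names(w) <- network$nodes$id
  w
}

#' Wait time charged at a node
#'
#' The wait applies when an agent passes through the node interior to its
#' path; the origin and the terminal node of a path incur no wait. A
#' per-node `wait_override` takes precedence; otherwise the configured
#' `intersection_wait` applies at signalized nodes (and, with
#' `wait_scope = "all_intersections"`, at every node of degree >= 3).
#'
#' @param network a `pedshed_network`
#' @param node a node id
#' @param config a `pedshed_config`
#' @return wait in seconds
#' @export
node_wait <- function(network, node, config) {
  w <- node_wait_vector(network, config)
  if (!node %in% names(w)) stop(sprintf("no such node id '%s'", node))
  unname(w[node])
}

# Directed-arc view of the network restricted to passable edges. Arcs carry
# the original edge id and the offsets (s_tail -> s_head) they span, so
# coverage computed on arcs maps straight back to edge geometry.
base_arc_graph <- function(network, config) {
  nodes <- network$nodes
  w <- node_wait_vector(network, config)
  edges <- network$edges[network$edges$passable, , drop = FALSE]
  time_mode <- config$budget_kind == "time"
  if (nrow(edges)) {
    sp <- effective_speed(edges$gradient, config)
    base <- if (time_mode) edges$length / sp else edges$length
    arcs <- data.frame(
      tail = c(edges$from, edges$to),
      head = c(edges$to, edges$from),
      edge_id = c(edges$id, edges$id),
      s_tail = c(rep(0, nrow(edges)), edges$length),
      s_head = c(edges$length, rep(0, nrow(edges))),
      base = c(base, base),
      stringsAsFactors = FALSE
    )
  } else {
    arcs <- data.frame(tail = character(), head = character(),
                       edge_id = character(), s_tail = double(),
                       s_head = double(), base = double(),
                       stringsAsFactors = FALSE)
  }
  list(
    ids = nodes$id, x = nodes$x, y = nodes$y,
    w = w,                      # true waits in seconds per node id
    time_mode = time_mode,
    arcs = arcs,
    network = network
  )
}

# Insert a snapped location as a (temporary) vertex, splitting the arcs that
# span its offset. If the offset coincides with an existing vertex the
# existing id is returned instead.
insert_location <- function(aug, loc, new_id) {
  eps <- 1e-9
  edges <- aug$network$edges
  ei <- match(loc$edge_id, edges$id)
  if (is.na(ei)) stop(sprintf("location references unknown edge '%s'", loc$edge_id))
  if (!edges$passable[ei]) {
    stop(sprintf("location lies on impassable edge '%s'", loc$edge_id))
  }
  o <- loc$offset
  # existing vertex at this offset? (edge endpoints or a previous insertion)
  hit <- which(aug$arcs$edge_id == loc$edge_id &
                 abs(aug$arcs$s_tail - o) <= eps)
  if (length(hit)) return(list(aug = aug, id = aug$arcs$tail[hit[1]]))
  hit <- which(aug$arcs$edge_id == loc$edge_id &
                 abs(aug$arcs$s_head - o) <= eps)
  if (length(hit)) return(list(aug = aug, id = aug$arcs$head[hit[1]]))

  spans <- which(aug$arcs$edge_id == loc$edge_id &
                   pmin(aug$arcs$s_tail, aug$arcs$s_head) < o - eps &
                   pmax(aug$arcs$s_tail, aug$arcs$s_head) > o + eps)
  if (!length(spans)) stop("location offset is outside the edge")
  a <- aug$arcs[spans, , drop = FALSE]
  frac <- (o - a$s_tail) / (a$s_head - a$s_tail)
  first <- data.frame(tail = a$tail, head = new_id, edge_id = a$edge_id,
                      s_tail = a$s_tail, s_head = o, base = a$base * frac,
                      stringsAsFactors = FALSE)
  second <- data.frame(tail = new_id, head = a$head, edge_id = a$edge_id,
                       s_tail = o, s_head = a$s_head,
                       base = a$base * (1 - frac), stringsAsFactors = FALSE)
  aug$arcs <- rbind(aug$arcs[-spans, , drop = FALSE], first, second)
  rownames(aug$arcs) <- NULL
  aug$ids <- c(aug$ids, new_id)
  aug$x <- c(aug$x, loc$point[1])
  aug$y <- c(aug$y, loc$point[2])
  aug$w <- c(aug$w, stats::setNames(0, new_id))
  list(aug = aug, id = new_id)
}

# arc weights for shortest paths: traversal cost plus the wait charged at the
# arc's head. Subtracting the head's wait afterwards yields the arrival time
# at the head *before* waiting there, which makes origin and terminal nodes
# wait-free automatically.
arc_weights <- function(aug) {
  if (aug$time_mode) aug$arcs$base + unname(aug$w[aug$arcs$head]) else aug$arcs$base
}

# merge a set of [lo, hi] intervals into their union
merge_intervals <- function(lo, hi) {
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  out_lo <- lo[1]; out_hi <- hi[1]
  if (length(lo) > 1) {
    for (k in 2:length(lo)) {
      if (lo[k] <= out_hi[length(out_hi)] + 1e-9) {
        out_hi[length(out_hi)] <- max(out_hi[length(out_hi)], hi[k])
      } else {
        out_lo <- c(out_lo, lo[k]); out_hi <- c(out_hi, hi[k])
      }
    }
  }
  cbind(lo = out_lo, hi = out_hi)
}

#' Compute the time- or distance-budgeted walkshed from an origin
#'
#' Single-source shortest generalized costs over the noded network, where the
#' cost of a path is the sum of gradient-adjusted edge traversal times plus
#' intersection waits at interior nodes (time budget), or the sum of edge
#' lengths with waits costing nothing (distance budget). Edges the budget
#' covers entirely are reported as reached; edges where the budget runs out
#' part-way contribute frontier fragments cut exactly where the residual
#' budget reaches zero.
#'
#' @param network a `pedshed_network`
#' @param origin a `pedshed_location` from [snap_point()], or c(x, y)
#'   coordinates to snap automatically
#' @param config a `pedshed_config`
#' @return a `pedshed_reachability` with `arrival_times` (named seconds or
#'   meters for every node reached within budget, waits at the node itself
#'   excluded), `reached_edges`, `frontier_fragments`, `coverage` (merged
#'   covered intervals per edge), and `reached_length`
#' @export
compute_reachability <- function(network, origin, config) {
  stopifnot(inherits(network, "pedshed_network"), inherits(config, "pedshed_config"))
  if (is.numeric(origin)) origin <- snap_point(network, origin)
  stopifnot(inherits(origin, "pedshed_location"))

  aug <- base_arc_graph(network, config)
  ins <- insert_location(aug, origin, "@origin")
  aug <- ins$aug; origin_id <- ins$id
  if (nrow(aug$arcs) == 0) stop("network has no passable edges")

  g <- igraph::graph_from_data_frame(
    aug$arcs[, c("tail", "head")], directed = TRUE, vertices = aug$ids
  )
  dist_prime <- igraph::distances(
    g, v = origin_id, to = aug$ids, mode = "out", weights = arc_weights(aug)
  )[1, ]
  wv <- if (aug$time_mode) unname(aug$w[aug$ids]) else rep(0, length(aug$ids))
  arrival <- stats::setNames(as.numeric(dist_prime) - wv, aug$ids)
  arrival[origin_id] <- 0

  B <- config$budget
  # residual budget available when leaving each node (the node's own wait is
  # paid before continuing, except at the origin)
  leave_cost <- arrival + (if (aug$time_mode) unname(aug$w[aug$ids]) else 0)
  leave_cost[origin_id] <- 0

  at <- arrival[aug$arcs$tail]
  lc <- leave_cost[aug$arcs$tail]
  remain <- B - lc
  frac <- pmin(pmax(remain / aug$arcs$base, 0), 1)
  frac[!is.finite(at) | at > B + 1e-9] <- 0
  cov_s1 <- aug$arcs$s_tail
  cov_s2 <- aug$arcs$s_tail + frac * (aug$arcs$s_head - aug$arcs$s_tail)
  keep <- frac > 0
  cov <- data.frame(
    edge_id = aug$arcs$edge_id[keep],
    lo = pmin(cov_s1, cov_s2)[keep],
    hi = pmax(cov_s1, cov_s2)[keep],
    stringsAsFactors = FALSE
  )

  edges <- network$edges
  coverage <- data.frame(edge_id = character(), s0 = double(), s1 = double(),
                         stringsAsFactors = FALSE)
  if (nrow(cov)) {
    parts <- split(cov, cov$edge_id)
    coverage <- do.call(rbind, lapply(parts, function(p) {
      m <- merge_intervals(p$lo, p$hi)
      data.frame(edge_id = p$edge_id[1], s0 = m[, "lo"], s1 = m[, "hi"],
                 stringsAsFactors = FALSE)
    }))
    rownames(coverage) <- NULL
    # deterministic edge order
    coverage <- coverage[order(match(coverage$edge_id, edges$id), coverage$s0), ,
                         drop = FALSE]
  }

  el <- edges$length[match(coverage$edge_id, edges$id)]
  full <- coverage$s0 <= 1e-9 & coverage$s1 >= el - 1e-9
  reached_edges <- coverage$edge_id[full]
  frag <- coverage[!full, , drop = FALSE]
  frag_geom <- lapply(seq_len(nrow(frag)), function(i) {
    polyline_substring(edges$geometry[[match(frag$edge_id[i], edges$id)]],
                       frag$s0[i], frag$s1[i])
  })
  frag$geometry <- frag_geom

  arr_nodes <- arrival[network$nodes$id]
  arr_nodes <- arr_nodes[is.finite(arr_nodes) & arr_nodes <= B + 1e-9]

  structure(
    list(
      origin = origin,
      config = config,
      network = network,
      budget_kind = config$budget_kind,
      arrival_times = arr_nodes,
      reached_edges = reached_edges,
      frontier_fragments = frag,
      coverage = coverage,
      reached_length = if (nrow(coverage)) sum(coverage$s1 - coverage$s0) else 0
    ),
    class = "pedshed_reachability"
  )
}

#' @export
print.pedshed_reachability <- function(x, ...) {
  cat(sprintf(
    "<pedshed_reachability> %s budget %g: %d nodes reached, %d edges fully reached, %d frontier fragments, %.1f m of network covered\n",
    x$budget_kind, x$config$budget, length(x$arrival_times),
    length(x$reached_edges), nrow(x$frontier_fragments), x$reached_length
  ))
  invisible(x)
}

#' Sample random destinations on the network
#'
#' Destinations are distributed uniformly by network length over passable
#' edges (an edge is chosen with probability proportional to its length, the
#' offset uniformly along it), reproducibly from `config$seed`.
#'
#' @param network a `pedshed_network`
#' @param config a `pedshed_config` (uses `n_destinations` and `seed`)
#' @return list of `pedshed_location`
#' @export
sample_destinations <- function(network, config) {
  stopifnot(inherits(network, "pedshed_network"), inherits(config, "pedshed_config"))
  edges <- network$edges[network$edges$passable, , drop = FALSE]
  if (nrow(edges) == 0) stop("network has no passable edges to sample from")
  n <- config$n_destinations
  with_local_seed(config$seed, {
    ei <- sample.int(nrow(edges), n, replace = TRUE, prob = edges$length)
    off <- stats::runif(n) * edges$length[ei]
    lapply(seq_len(n), function(k) {
      pt <- polyline_point_at(edges$geometry[[ei[k]]], off[k])
      structure(
        list(edge_id = edges$id[ei[k]], offset = off[k], point = pt,
             snap_distance = 0),
        class = "pedshed_location"
      )
    })
  })
}

# A-Star over the directed arc view with the straight-line admissible
# heuristic (Euclidean distance, divided by the flat-ground walking speed in
# time mode; waits are nonnegative and gradients only slow agents down, so
# the heuristic never overestimates). Returns Inf cost when unreachable.
astar_route <- function(aug, config, from_id, to_id) {
  ids <- aug$ids
  n <- length(ids)
  src <- match(from_id, ids); dst <- match(to_id, ids)
  tail_i <- match(aug$arcs$tail, ids)
  head_i <- match(aug$arcs$head, ids)
  wt <- arc_weights(aug)
  by_tail <- split(seq_along(tail_i), tail_i)
  h <- sqrt((aug$x - aug$x[dst])^2 + (aug$y - aug$y[dst])^2)
  if (aug$time_mode) h <- h / config$walking_speed
  g <- rep(Inf, n); g[src] <- 0
  fopen <- rep(Inf, n); fopen[src] <- h[src]
  prev_arc <- rep(NA_integer_, n)
  repeat {
    u <- which.min(fopen)
    if (!is.finite(fopen[u])) return(list(cost = Inf, arc_path = integer()))
    if (u == dst) break
    fopen[u] <- Inf
    out <- by_tail[[as.character(u)]]
    if (is.null(out)) next
    cand <- g[u] + wt[out]
    v <- head_i[out]
    better <- cand < g[v] - 1e-12
    if (any(better)) {
      vb <- v[better]
      g[vb] <- cand[better]
      prev_arc[vb] <- out[better]
      fopen[vb] <- g[vb] + h[vb]
    }
  }
  # reconstruct arc path
  path <- integer()
  v <- dst
  while (!is.na(prev_arc[v])) {
    path <- c(prev_arc[v], path)
    v <- tail_i[prev_arc[v]]
  }
  # subtract the head wait folded into the last arc: arrival at the terminal
  # is wait-free
  cost <- g[dst]
  if (aug$time_mode && dst <= length(aug$w)) cost <- cost - unname(aug$w[ids[dst]])
  list(cost = cost, arc_path = path)
}

#' Simulate agents walking from the origin to sampled destinations
#'
#' One agent per destination from [sample_destinations()]. Each agent follows
#' the cost-optimal path (A-Star with the straight-line admissible
#' heuristic), waits at eligible interior intersections, and stops where the
#' time or distance budget is exhausted. Paths are rendered as points spaced
#' `trace_spacing` meters apart along the walk, each carrying the elapsed
#' time in seconds (waits included, so timestamps jump by the wait at
#' signalized crossings).
#'
#' @inheritParams compute_reachability
#' @param destinations optional list of `pedshed_location` destinations; by
#'   default they are sampled with [sample_destinations()]
#' @return a `pedshed_traces` list of agent traces; each trace has
#'   `agent_id`, `destination`, `node_path`, `crossed_nodes` (interior nodes
#'   actually passed), `points` (x, y, t data.frame), `path_cost` and
#'   `completed`
#' @export
simulate_agents <- function(network, origin, config, destinations = NULL) {
  stopifnot(inherits(network, "pedshed_network"), inherits(config, "pedshed_config"))
  if (is.numeric(origin)) origin <- snap_point(network, origin)
  dests <- if (is.null(destinations)) sample_destinations(network, config) else destinations

  base <- base_arc_graph(network, config)
  ins <- insert_location(base, origin, "@origin")
  base <- ins$aug; origin_id <- ins$id
  w_true <- c(node_wait_vector(network, config),
              stats::setNames(0, "@origin"), stats::setNames(0, "@dest"))

  edges <- network$edges
  sp_edge <- stats::setNames(effective_speed(edges$gradient, config), edges$id)

  traces <- vector("list", length(dests))
  for (k in seq_along(dests)) {
    ins2 <- tryCatch(insert_location(base, dests[[k]], "@dest"),
                     error = function(e) NULL)
    if (is.null(ins2)) {
      traces[[k]] <- empty_trace(k, dests[[k]], origin)
      next
    }
    aug <- ins2$aug; dest_id <- ins2$id
    route <- astar_route(aug, config, origin_id, dest_id)
    if (!is.finite(route$cost) || length(route$arc_path) == 0) {
      tr <- empty_trace(k, dests[[k]], origin)
      tr$completed <- length(route$arc_path) == 0 && is.finite(route$cost)
      traces[[k]] <- tr
      next
    }
    traces[[k]] <- build_trace(k, aug, route, dests[[k]], origin, config,
                               w_true, sp_edge)
  }
  structure(traces, class = "pedshed_traces",
            network = network, config = config, origin = origin)
}

empty_trace <- function(agent_id, destination, origin) {
  structure(
    list(agent_id = agent_id, destination = destination,
         node_path = character(), crossed_nodes = character(),
         points = data.frame(x = origin$point[1], y = origin$point[2], t = 0),
         path_cost = Inf, completed = FALSE),
    class = "pedshed_trace"
  )
}

# turn an arc path into an equally spaced, time-stamped trace, truncated at
# the budget
build_trace <- function(agent_id, aug, route, destination, origin, config,
                        w_true, sp_edge) {
  arcs <- aug$arcs[route$arc_path, , drop = FALSE]
  edges <- aug$network$edges
  npieces <- nrow(arcs)
  piece_len <- abs(arcs$s_head - arcs$s_tail)
  piece_speed <- unname(sp_edge[arcs$edge_id])
  end_node <- arcs$head               # node reached after each piece
  # waits paid after each piece, at interior nodes only
  wait_after <- unname(w_true[end_node])
  wait_after[npieces] <- 0

  S <- c(0, cumsum(piece_len))        # path offset at piece boundaries
  piece_time <- piece_len / piece_speed
  T <- c(0, cumsum(piece_time + wait_after))  # departure-time at boundaries
  arrive_T <- T[-length(T)] + piece_time      # arrival time at each piece end
  total_len <- S[length(S)]

  # budget truncation
  B <- config$budget
  if (config$budget_kind == "distance") {
    s_cut <- min(total_len, B)
    # time at s_cut for bookkeeping (not used for the cut itself)
  } else {
    s_cut <- total_len
    if (T[length(T)] - 0 > B + 1e-9 || arrive_T[npieces] > B + 1e-9) {
      s_cut <- 0
      for (i in seq_len(npieces)) {
        if (arrive_T[i] <= B + 1e-9) {
          s_cut <- S[i + 1]
          if (i < npieces && T[i + 1] > B + 1e-9) break  # stuck mid-wait
        } else {
          rem <- B - T[i]
          if (rem > 0) s_cut <- S[i] + rem * piece_speed[i]
          break
        }
      }
    }
  }
  completed <- s_cut >= total_len - 1e-9

  t_at <- function(s) {
    # piece index such that S[i] <= s <= S[i+1]; exact boundaries take the
    # arrival time (before any wait there)
    vapply(s, function(sv) {
      i <- findInterval(sv, S, rightmost.closed = TRUE)
      i <- min(max(i, 1), npieces)
      if (sv <= S[i] + 1e-12 && i > 1) {
        arrive_T[i - 1]
      } else if (sv >= S[i + 1] - 1e-12) {
        arrive_T[i]
      } else {
        T[i] + (sv - S[i]) / piece_speed[i]
      }
    }, numeric(1))
  }

  svals <- seq(0, s_cut, by = config$trace_spacing)
  if (length(svals) == 0 || svals[length(svals)] < s_cut - 1e-9) {
    svals <- c(svals, s_cut)
  }

  # path polyline
  coords <- lapply(seq_len(npieces), function(i) {
    gi <- edges$geometry[[match(arcs$edge_id[i], edges$id)]]
    sub <- polyline_substring(gi, min(arcs$s_tail[i], arcs$s_head[i]),
                              max(arcs$s_tail[i], arcs$s_head[i]))
    if (arcs$s_tail[i] > arcs$s_head[i]) sub <- sub[rev(seq_len(nrow(sub))), , drop = FALSE]
    sub
  })
  path_line <- coords[[1]]
  if (npieces > 1) {
    for (i in 2:npieces) path_line <- rbind(path_line, coords[[i]][-1, , drop = FALSE])
  }
  pts <- t(vapply(svals, function(sv) polyline_point_at(path_line, sv), numeric(2)))

  real <- function(v) v[!startsWith(v, "@")]
  path_nodes <- c(arcs$tail[1], arcs$head)
  interior <- if (npieces > 1) arcs$head[seq_len(npieces - 1)] else character()
  crossed <- interior[S[seq_len(max(npieces - 1, 0)) + 1] < s_cut - 1e-9]

  structure(
    list(
      agent_id = agent_id,
      destination = destination,
      node_path = real(path_nodes),
      crossed_nodes = real(crossed),
      points = data.frame(x = pts[, 1], y = pts[, 2], t = t_at(svals)),
      path_cost = route$cost,
      completed = completed
    ),
    class = "pedshed_trace"
  )
}

#' @export
print.pedshed_traces <- function(x, ...) {
  done <- sum(vapply(x, function(tr) tr$completed, logical(1)))
  cat(sprintf("<pedshed_traces> %d agents (%d completed), %d trace points\n",
              length(x), done,
              sum(vapply(x, function(tr) nrow(tr$points), integer(1)))))
  invisible(x)
}
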