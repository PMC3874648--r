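# traversal costs, waits, reachability, destination sampling, agent routing

three_edge_corridor <- function() {
  net <- build_network(
    list(cbind(c(0, 100), c(0, 0)), cbind(c(100, 200), c(0, 0)),
         cbind(c(200, 300), c(0, 0))),
    crs_units = "m"
  )
  net$nodes$signalized[net$nodes$x %in% c(100, 200)] <- TRUE
  net
}

test_that("edge traversal time follows the gradient-adjusted speed", {
  cfg <- simulation_config(walking_speed = 2, max_time = 600)
  edge <- list(length = 100, gradient = NA_real_, passable = TRUE)
  expect_equal(edge_traversal_time(edge, cfg), 50)

  cfg2 <- simulation_config(walking_speed = 1, max_time = 600,
                            gradient_penalty = 0.05)
  expect_equal(edge_traversal_time(list(length = 100, gradient = 10,
                                        passable = TRUE), cfg2), 200)
  # penalty 0 ignores gradient entirely
  cfg3 <- simulation_config(walking_speed = 1, max_time = 600)
  expect_equal(edge_traversal_time(list(length = 100, gradient = 40,
                                        passable = TRUE), cfg3), 100)
  # speed floor at 20%
  cfg4 <- simulation_config(walking_speed = 1, max_time = 600,
                            gradient_penalty = 0.1)
  expect_equal(edge_traversal_time(list(length = 100, gradient = 50,
                                        passable = TRUE), cfg4), 100 / 0.2)
  expect_error(edge_traversal_time(list(length = 100, gradient = NA,
                                        passable = FALSE), cfg), "impassable")
})

test_that("node_wait applies signals, scope and overrides correctly", {
  net <- three_edge_corridor()
  cfg <- simulation_config(walking_speed = 1, max_time = 600,
                           intersection_wait = 30)
  sig <- net$nodes$id[net$nodes$x == 100]
  end <- net$nodes$id[net$nodes$x == 0]
  expect_equal(node_wait(net, sig, cfg), 30)
  expect_equal(node_wait(net, end, cfg), 0)
  # degree-2 unsignalized vertex waits only under all_intersections if deg >= 3
  net2 <- net
  net2$nodes$signalized[] <- FALSE
  cfg_all <- simulation_config(walking_speed = 1, max_time = 600,
                               intersection_wait = 30,
                               wait_scope = "all_intersections")
  expect_equal(node_wait(net2, sig, cfg_all), 0)  # corridor nodes are degree 2
  grid <- make_grid(3, 3, 100)
  center <- grid$nodes$id[grid$nodes$x == 100 & grid$nodes$y == 100]
  expect_equal(node_wait(grid, center, cfg_all), 30)
  # override beats the configured wait
  net3 <- net
  net3$nodes$wait_override[net3$nodes$id == sig] <- 45
  cfg10 <- simulation_config(walking_speed = 1, max_time = 600,
                             intersection_wait = 10)
  expect_equal(node_wait(net3, sig, cfg10), 45)
})

test_that("straight-road reachability is r = v*t in both directions", {
  road <- make_single_road(3000)
  cfg <- simulation_config(walking_speed = 1.5, max_time = 600,
                           n_destinations = 3)
  r <- compute_reachability(road, snap_point(road, c(1500, 0)), cfg)
  expect_equal(r$reached_length, 1800)
  expect_length(r$arrival_times, 0)  # far endpoints unreached
  expect_equal(nrow(r$frontier_fragments), 1)  # one merged interval around origin
  expect_equal(r$coverage$s0, 600)
  expect_equal(r$coverage$s1, 2400)
})

test_that("waits at signalized interior nodes add exactly to arrivals", {
  net <- three_edge_corridor()
  cfg <- simulation_config(walking_speed = 1, max_time = 360,
                           intersection_wait = 30, n_destinations = 3)
  r <- compute_reachability(net, snap_point(net, c(0, 0)), cfg)
  far <- net$nodes$id[net$nodes$x == 300]
  expect_equal(unname(r$arrival_times[far]), 360)  # 300 s travel + 2 x 30 s
  expect_length(r$reached_edges, 3)

  # distance mode is unaffected by waits
  cfgd <- simulation_config(walking_speed = 1, max_distance = 300,
                            intersection_wait = 60, n_destinations = 3)
  rd <- compute_reachability(net, snap_point(net, c(0, 0)), cfgd)
  expect_equal(unname(rd$arrival_times[far]), 300)
  expect_equal(rd$reached_length, 300)
})

test_that("arrival times match the Bellman-Ford oracle on random networks", {
  set.seed(202)
  for (rep in 1:25) {
    net <- random_test_network(sample(8:16, 1))
    cfg <- random_test_config()
    origin <- random_origin(net)
    r <- compute_reachability(net, origin, cfg)
    oracle <- oracle_arrivals(net, origin, cfg)
    oracle <- oracle[is.finite(oracle) & oracle <= cfg$budget + 1e-9]
    expect_setequal(names(r$arrival_times), names(oracle))
    expect_equal(r$arrival_times[names(oracle)], oracle, tolerance = 1e-9)
  }
})

test_that("frontier fragments stop exactly where the budget runs out", {
  set.seed(77)
  for (rep in 1:10) {
    net <- random_test_network(10)
    cfg <- random_test_config()
    origin <- random_origin(net)
    r <- compute_reachability(net, origin, cfg)
    frag <- r$frontier_fragments
    if (nrow(frag) == 0) next
    arr <- oracle_arrivals(net, origin, cfg)
    w <- pedshed:::node_wait_vector(net, cfg)
    if (cfg$budget_kind == "distance") w[] <- 0
    for (i in seq_len(nrow(frag))) {
      e <- net$edges[match(frag$edge_id[i], net$edges$id), ]
      sp <- if (cfg$budget_kind == "time")
        pedshed:::effective_speed(e$gradient, cfg) else 1
      on_origin_edge <- e$id == origin$edge_id
      cost_to <- function(s) {
        cands <- c(
          arr[e$from] + w[e$from] + s / sp,
          arr[e$to] + w[e$to] + (e$length - s) / sp
        )
        if (on_origin_edge) cands <- c(cands, abs(s - origin$offset) / sp)
        min(cands)
      }
      for (cut in c(frag$s0[i], frag$s1[i])) {
        if (cut > 1e-6 && cut < e$length - 1e-6) {
          expect_equal(cost_to(cut), cfg$budget, tolerance = 1e-6)
        }
      }
    }
  }
})

test_that("a barrier edge removes the far side entirely", {
  net <- build_network(
    list(cbind(c(0, 100), c(0, 0)), cbind(c(100, 200), c(0, 0)),
         cbind(c(200, 300), c(0, 0))),
    attributes = data.frame(gradient = NA, passable = c(TRUE, FALSE, TRUE)),
    crs_units = "m"
  )
  cfg <- simulation_config(walking_speed = 2, max_time = 1200, n_destinations = 3)
  r <- compute_reachability(net, snap_point(net, c(0, 0)), cfg)
  far <- net$nodes$id[net$nodes$x >= 200]
  expect_false(any(far %in% names(r$arrival_times)))
  expect_equal(r$reached_length, 100)
})

test_that("destination sampling is seeded, on-network and length-proportional", {
  net <- build_network(
    list(cbind(c(0, 100), c(0, 0)), cbind(c(100, 400), c(0, 0))),
    crs_units = "m"
  )
  cfg <- simulation_config(walking_speed = 1, max_time = 600,
                           n_destinations = 10000, seed = 99)
  d1 <- sample_destinations(net, cfg)
  d2 <- sample_destinations(net, cfg)
  expect_identical(d1, d2)
  share <- mean(vapply(d1, function(l) l$edge_id, character(1)) == "e1")
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(share - 0.25), 3 * se)
  # single-edge network: everything lands on that edge
  road <- make_single_road(100)
  cfg1 <- simulation_config(walking_speed = 1, max_time = 60, n_destinations = 20)
  expect_true(all(vapply(sample_destinations(road, cfg1),
                         function(l) l$edge_id, character(1)) == "e1"))
})

test_that("A-Star path costs equal Dijkstra on random origin-destination pairs", {
  set.seed(303)
  for (rep in 1:10) {
    net <- random_test_network(12)
    cfg <- random_test_config()
    aug <- pedshed:::base_arc_graph(net, cfg)
    if (nrow(aug$arcs) == 0) next
    g <- igraph::graph_from_data_frame(aug$arcs[, c("tail", "head")],
                                       directed = TRUE, vertices = aug$ids)
    dmat <- igraph::distances(g, mode = "out",
                              weights = pedshed:::arc_weights(aug))
    for (k in 1:10) {
      ab <- sample(aug$ids, 2)
      route <- pedshed:::astar_route(aug, cfg, ab[1], ab[2])
      want <- dmat[ab[1], ab[2]]
      if (aug$time_mode && is.finite(want)) {
        want <- want - unname(aug$w[ab[2]])
      }
      if (!is.finite(want)) {
        expect_false(is.finite(route$cost))
      } else {
        expect_equal(route$cost, want, tolerance = 1e-9)
      }
    }
  }
})

test_that("traces are equally spaced with cumulative, wait-aware timestamps", {
  road <- make_single_road(100)
  cfg <- simulation_config(walking_speed = 1, max_time = 200,
                           n_destinations = 1, trace_spacing = 10)
  dest <- snap_point(road, c(100, 0))
  tr <- simulate_agents(road, snap_point(road, c(0, 0)), cfg,
                        destinations = list(dest))
  pts <- tr[[1]]$points
  expect_equal(nrow(pts), 11)
  expect_equal(pts$t, seq(0, 100, by = 10))
  expect_equal(pts$x, seq(0, 100, by = 10))
  expect_true(tr[[1]]$completed)

  # corridor with waits: the final timestamp matches the reachability arrival
  net <- three_edge_corridor()
  cfgw <- simulation_config(walking_speed = 1, max_time = 360,
                            intersection_wait = 30, n_destinations = 1,
                            trace_spacing = 25)
  dest2 <- snap_point(net, c(300, 0))
  trw <- simulate_agents(net, snap_point(net, c(0, 0)), cfgw,
                         destinations = list(dest2))
  ptsw <- trw[[1]]$points
  expect_true(trw[[1]]$completed)
  expect_equal(ptsw$t[nrow(ptsw)], 360)
  expect_true(all(diff(ptsw$t) > 0))
  # spacing never exceeds trace_spacing along the path
  expect_true(all(diff(ptsw$x) <= 25 + 1e-9))
  # the timestamp jump across each signalized node includes the 30 s wait
  before100 <- max(which(ptsw$x <= 100))
  expect_equal(ptsw$t[before100 + 1] - ptsw$t[before100],
               30 + (ptsw$x[before100 + 1] - ptsw$x[before100]) / 1)
})

test_that("agents stop at the frontier when the budget is too small", {
  road <- make_single_road(1000)
  cfg <- simulation_config(walking_speed = 1, max_time = 300,
                           n_destinations = 1, trace_spacing = 50)
  dest <- snap_point(road, c(900, 0))
  tr <- simulate_agents(road, snap_point(road, c(0, 0)), cfg,
                        destinations = list(dest))
  expect_false(tr[[1]]$completed)
  pts <- tr[[1]]$points
  expect_equal(pts$x[nrow(pts)], 300)
  expect_equal(pts$t[nrow(pts)], 300)
})

test_that("agents to a disconnected component stay at the origin, not completed", {
  net <- build_network(
    list(cbind(c(0, 100), c(0, 0)), cbind(c(0, 100), c(500, 500))),
    crs_units = "m"
  )
  cfg <- simulation_config(walking_speed = 1, max_time = 600, n_destinations = 1)
  dest <- snap_point(net, c(50, 500))
  tr <- simulate_agents(net, snap_point(net, c(0, 0)), cfg,
                        destinations = list(dest))
  expect_false(tr[[1]]$completed)
  expect_equal(nrow(tr[[1]]$points), 1)
  expect_equal(tr[[1]]$points$t, 0)
})

test_that("reached length is monotone in budget and speed, antitone in wait", {
  grid <- make_grid(5, 5, 100, signal_fraction = 1, seed = 4)
  origin <- c(200, 200)
  reach_len <- function(speed, time, wait) {
    cfg <- simulation_config(walking_speed = speed, max_time = time,
                             intersection_wait = wait, n_destinations = 2)
    compute_reachability(grid, snap_point(grid, origin), cfg)$reached_length
  }
  expect_true(all(diff(sapply(c(100, 200, 400, 800), function(t)
    reach_len(1.2, t, 20))) >= -1e-9))
  expect_true(all(diff(sapply(c(0.5, 1, 1.5, 2), function(v)
    reach_len(v, 400, 20))) >= -1e-9))
  expect_true(all(diff(sapply(c(0, 20, 40, 60), function(w)
    reach_len(1.2, 400, w))) <= 1e-9))
})
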