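# Simulation configuration: the user-facing dials of the model, with the
# same hard ranges the tool exposes (speed up to 2 m/s, time up to 20 min,
# intersection wait up to 60 s, and a time XOR distance budget).

#' Create a simulation configuration
#'
#' Exactly one of `max_time` and `max_distance` must be set: the walkshed is
#' budgeted either in seconds of walking (waits at intersections consume the
#' budget) or in meters along the network (waits consume no distance).
#'
#' @param walking_speed walking speed in m/s, in (0, 2]
#' @param max_time time budget in seconds, in (0, 1200]; mutually exclusive
#'   with `max_distance`
#' @param max_distance distance budget in meters (> 0)
#' @param intersection_wait seconds waited when crossing an eligible
#'   intersection, in [0, 60]
#' @param wait_scope `"signalized_only"` (default: only nodes flagged as
#'   signalized wait) or `"all_intersections"` (every node of degree >= 3)
#' @param gradient_penalty fractional speed reduction per percent slope, in
#'   [0, 0.1]; effective speed never drops below 20% of `walking_speed`
#' @param n_destinations number of randomly sampled destinations (one agent
#'   each)
#' @param seed integer seed for destination sampling
#' @param trace_spacing spacing in meters between consecutive time-stamped
#'   trace points
#' @param buffer_width half-width in meters of the catchment buffer around
#'   reached streets
#' @param enforce_limits set FALSE to lift the slider caps (research use);
#'   positivity and the budget XOR rule are always enforced
#' @return a `pedshed_config` list
#' @export
simulation_config <- function(walking_speed = 1.4,
                              max_time = NULL,
                              max_distance = NULL,
                              intersection_wait = 0,
                              wait_scope = c("signalized_only", "all_intersections"),
                              gradient_penalty = 0,
                              n_destinations = 500,
                              seed = 1L,
                              trace_spacing = 5,
                              buffer_width = 50,
                              enforce_limits = TRUE) {
  wait_scope <- match.arg(wait_scope)
  has_time <- !is.null(max_time) && !is.na(max_time)
  has_dist <- !is.null(max_distance) && !is.na(max_distance)
  if (has_time == has_dist) {
    stop("set a maximum time or a maximum distance, but not both parameters ",
         "simultaneously (and not neither)")
  }
  if (!is.numeric(walking_speed) || walking_speed <= 0) {
    stop("walking_speed must be > 0 m/s")
  }
  if (enforce_limits && walking_speed > 2) {
    stop("walking_speed exceeds the 2 m/s cap")
  }
  if (has_time) {
    if (max_time <= 0) stop("max_time must be > 0 s")
    if (enforce_limits && max_time > 1200) {
      stop("max_time exceeds the 1200 s (20 minute) cap")
    }
  }
  if (has_dist && max_distance <= 0) stop("max_distance must be > 0 m")
  if (intersection_wait < 0) stop("intersection_wait must be >= 0 s")
  if (enforce_limits && intersection_wait > 60) {
    stop("intersection_wait exceeds the 60 s cap")
  }
  if (gradient_penalty < 0 || gradient_penalty > 0.1) {
    stop("gradient_penalty must be in [0, 0.1]")
  }
  if (n_destinations < 1) stop("n_destinations must be >= 1")
  if (trace_spacing <= 0) stop("trace_spacing must be > 0 m")
  if (buffer_width <= 0) stop("buffer_width must be > 0 m")
  structure(
    list(
      walking_speed = walking_speed,
      max_time = if (has_time) max_time else NULL,
      max_distance = if (has_dist) max_distance else NULL,
      budget_kind = if (has_time) "time" else "distance",
      budget = if (has_time) max_time else max_distance,
      intersection_wait = intersection_wait,
      wait_scope = wait_scope,
      gradient_penalty = gradient_penalty,
      n_destinations = as.integer(n_destinations),
      seed = as.integer(seed),
      trace_spacing = trace_spacing,
      buffer_width = buffer_width,
      enforce_limits = enforce_limits
    ),
    class = "pedshed_config"
  )
}

#' @export
print.pedshed_config <- function(x, ...) {
  budget <- if (x$budget_kind == "time") {
    sprintf("max_time %g s", x$max_time)
  } else {
    sprintf("max_distance %g m", x$max_distance)
  }
  cat(sprintf(
    "<pedshed_config> speed %g m/s, %s, wait %g s (%s), %d destinations, seed %d\n",
    x$walking_speed, budget, x$intersection_wait, x$wait_scope,
    x$n_destinations, x$seed
  ))
  invisible(x)
}

# run the RNG-dependent `code` under `seed` without disturbing the caller's
# RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}
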