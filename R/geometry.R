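# Low-level planar geometry on projected metric coordinates: polyline
# arc-length arithmetic, segment-segment intersection, point-to-segment
# projection, and the buffered-network ("capsule union") machinery used for
# catchment polygons. Everything here is pure base R and deterministic.

.PEDSHED_EPS <- 1e-9

#' Arc length of a polyline
#' @param coords two-column numeric matrix of vertices
#' @return length in the units of the coordinates (meters)
#' @keywords internal
#' @noRd
polyline_length <- function(coords) {
  if (is.null(coords) || nrow(coords) < 2) return(0)
  sum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2))
}

# coerce to a double matrix and drop consecutive duplicate vertices
clean_polyline <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("polyline must have two coordinate columns")
  storage.mode(coords) <- "double"
  if (anyNA(coords) || any(!is.finite(coords))) {
    stop("polyline contains non-finite coordinates")
  }
  if (nrow(coords) >= 2) {
    keep <- c(TRUE, sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2) > 0)
    coords <- coords[keep, , drop = FALSE]
  }
  coords
}

# cumulative arc length at each vertex (starts at 0)
polyline_cumlen <- function(coords) {
  c(0, cumsum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)))
}

#' Point at arc length s along a polyline
#' @keywords internal
#' @noRd
polyline_point_at <- function(coords, s) {
  cum <- polyline_cumlen(coords)
  L <- cum[length(cum)]
  s <- min(max(s, 0), L)
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1), nrow(coords) - 1)
  seg <- cum[i + 1] - cum[i]
  t <- if (seg > 0) (s - cum[i]) / seg else 0
  c(
    coords[i, 1] + t * (coords[i + 1, 1] - coords[i, 1]),
    coords[i, 2] + t * (coords[i + 1, 2] - coords[i, 2])
  )
}

#' Sub-polyline between arc lengths s0 and s1 (s0 < s1), keeping interior
#' vertices
#' @keywords internal
#' @noRd
polyline_substring <- function(coords, s0, s1) {
  cum <- polyline_cumlen(coords)
  L <- cum[length(cum)]
  s0 <- min(max(s0, 0), L)
  s1 <- min(max(s1, 0), L)
  if (s1 < s0) { tmp <- s0; s0 <- s1; s1 <- tmp }
  p0 <- polyline_point_at(coords, s0)
  p1 <- polyline_point_at(coords, s1)
  mid <- which(cum > s0 + .PEDSHED_EPS & cum < s1 - .PEDSHED_EPS)
  out <- rbind(p0, coords[mid, , drop = FALSE], p1)
  rownames(out) <- NULL
  clean_polyline(out)
}

# Explode a polyline into a segment table (one row per constituent segment)
# with the cumulative start offset of each segment along the polyline.
polyline_segments <- function(coords) {
  n <- nrow(coords)
  if (n < 2) {
    return(data.frame(x1 = double(), y1 = double(), x2 = double(),
                      y2 = double(), s0 = double(), len = double()))
  }
  len <- sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)
  data.frame(
    x1 = coords[-n, 1], y1 = coords[-n, 2],
    x2 = coords[-1, 1], y2 = coords[-1, 2],
    s0 = c(0, cumsum(len))[-n], len = len
  )
}

# Intersections of one segment (a1->a2) against many segments (vectors
# bx1, ...). Returns a data.frame with parameters t (on a) and u (on b) in
# [0, 1] and the intersection coordinates. Parallel pairs are skipped
# (endpoint-on-line contacts are recovered by the projection pass in the
# noding code).
segment_intersections <- function(ax1, ay1, ax2, ay2, bx1, by1, bx2, by2) {
  rx <- ax2 - ax1; ry <- ay2 - ay1
  sx <- bx2 - bx1; sy <- by2 - by1
  denom <- rx * sy - ry * sx
  qpx <- bx1 - ax1; qpy <- by1 - ay1
  ok <- abs(denom) > .PEDSHED_EPS * (abs(rx) + abs(ry)) * (abs(sx) + abs(sy) + 1)
  t <- ifelse(ok, (qpx * sy - qpy * sx) / denom, NA_real_)
  u <- ifelse(ok, (qpx * ry - qpy * rx) / denom, NA_real_)
  tol <- 1e-9
  hit <- ok & t >= -tol & t <= 1 + tol & u >= -tol & u <= 1 + tol
  idx <- which(hit)
  data.frame(
    i = idx,
    t = pmin(pmax(t[idx], 0), 1),
    u = pmin(pmax(u[idx], 0), 1),
    x = ax1 + pmin(pmax(t[idx], 0), 1) * rx,
    y = ay1 + pmin(pmax(t[idx], 0), 1) * ry
  )
}

# Project a point onto many segments at once. Returns per-segment parameter
# t in [0,1], squared distance, and foot-point coordinates.
point_segment_projection <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  t <- ifelse(l2 > 0, ((px - x1) * dx + (py - y1) * dy) / l2, 0)
  t <- pmin(pmax(t, 0), 1)
  qx <- x1 + t * dx; qy <- y1 + t * dy
  data.frame(t = t, dist2 = (px - qx)^2 + (py - qy)^2, qx = qx, qy = qy)
}

# Signed (shoelace) area of a closed ring (first point need not repeat last).
ring_signed_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# Even-odd point-in-ring test.
point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  xi <- x; yi <- y; xj <- x[j]; yj <- y[j]
  cross <- ((yi > py) != (yj > py)) &
    (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
  (sum(cross) %% 2) == 1
}

# Minimum distance from a single point to a set of segments (data.frame with
# x1,y1,x2,y2), vectorized over the segments. Used for contour-ring
# classification.
min_dist_to_segments <- function(px, py, segs) {
  dx <- segs$x2 - segs$x1
  dy <- segs$y2 - segs$y1
  l2 <- dx * dx + dy * dy
  t <- ifelse(l2 > 0, ((px - segs$x1) * dx + (py - segs$y1) * dy) / l2, 0)
  t <- pmin(pmax(t, 0), 1)
  sqrt(min((px - (segs$x1 + t * dx))^2 + (py - (segs$y1 + t * dy))^2))
}

# Exact Euclidean distance field from a segment set, evaluated on a regular
# grid. Each segment only touches the grid cells inside its padded bounding
# box. Returns a matrix z with dim c(length(xs), length(ys)).
distance_field <- function(segs, xs, ys, max_dist) {
  h <- xs[2] - xs[1]
  z <- matrix(Inf, nrow = length(xs), ncol = length(ys))
  pad <- max_dist + 2 * h
  for (k in seq_len(nrow(segs))) {
    x1 <- segs$x1[k]; y1 <- segs$y1[k]; x2 <- segs$x2[k]; y2 <- segs$y2[k]
    ix0 <- max(1L, floor((min(x1, x2) - pad - xs[1]) / h) + 1L)
    ix1 <- min(length(xs), ceiling((max(x1, x2) + pad - xs[1]) / h) + 1L)
    iy0 <- max(1L, floor((min(y1, y2) - pad - ys[1]) / h) + 1L)
    iy1 <- min(length(ys), ceiling((max(y1, y2) + pad - ys[1]) / h) + 1L)
    if (ix0 > ix1 || iy0 > iy1) next
    gx <- xs[ix0:ix1]; gy <- ys[iy0:iy1]
    nx <- length(gx); ny <- length(gy)
    X <- matrix(gx, nrow = nx, ncol = ny)
    Y <- matrix(gy, nrow = nx, ncol = ny, byrow = TRUE)
    dx <- x2 - x1; dy <- y2 - y1
    l2 <- dx * dx + dy * dy
    if (l2 > 0) {
      t <- ((X - x1) * dx + (Y - y1) * dy) / l2
      t[t < 0] <- 0; t[t > 1] <- 1
    } else {
      t <- 0
    }
    D <- sqrt((X - (x1 + t * dx))^2 + (Y - (y1 + t * dy))^2)
    z[ix0:ix1, iy0:iy1] <- pmin(z[ix0:ix1, iy0:iy1], D)
  }
  z
}

#' Buffered union of segments ("capsule union") as contour rings
#'
#' Computes the region within `width` of a set of segments by contouring an
#' exact distance field at level `width` (marching squares). Returns the
#' rings, each tagged as outer boundary (+) or hole (-), and the resulting
#' net area. The grid can be anchored to a fixed bounding box so that areas
#' computed for growing segment sets on the same network are monotone.
#'
#' @param segs data.frame with columns x1, y1, x2, y2
#' @param width buffer half-width in meters (> 0)
#' @param resolution grid spacing in meters; capped at `width / 3`
#' @param bbox optional c(xmin, xmax, ymin, ymax) anchor; defaults to the
#'   segment bounding box
#' @return list with `rings` (list of two-column matrices), `ring_sign`
#'   (+1 outer / -1 hole), `area` (m^2), `resolution`
#' @keywords internal
#' @noRd
capsule_union <- function(segs, width, resolution = width / 10, bbox = NULL) {
  if (width <= 0) stop("buffer width must be > 0")
  if (nrow(segs) == 0) {
    return(list(rings = list(), ring_sign = integer(), area = 0,
                resolution = resolution))
  }
  h <- min(resolution, width / 3)
  if (is.null(bbox)) {
    bbox <- c(min(segs$x1, segs$x2), max(segs$x1, segs$x2),
              min(segs$y1, segs$y2), max(segs$y1, segs$y2))
  }
  pad <- width + 3 * h
  # offset the grid anchor by an irrational fraction of the cell size so
  # field values never coincide exactly with the contour level on axis-aligned
  # networks (exact ties degrade contourLines); linear-field regions still
  # contour exactly under interpolation
  shift <- h / pi
  xs <- seq(bbox[1] - pad - shift, bbox[2] + pad + h, by = h)
  ys <- seq(bbox[3] - pad - shift, bbox[4] + pad + h, by = h)
  z <- distance_field(segs, xs, ys, width)
  # contourLines wants finite values; anything far away is simply "outside"
  big <- width * 4 + 4 * h
  z[!is.finite(z) | z > big] <- big
  cl <- grDevices::contourLines(xs, ys, z, levels = width)
  rings <- list()
  sign <- integer()
  for (cc in cl) {
    ring <- cbind(cc$x, cc$y)
    # drop the duplicated closing vertex if present
    n <- nrow(ring)
    if (n >= 2 && all(abs(ring[1, ] - ring[n, ]) < 1e-12)) {
      ring <- ring[-n, , drop = FALSE]
    }
    if (nrow(ring) < 3) next
    a <- ring_signed_area(ring)
    if (abs(a) < (h * h) / 100) next
    # classify outer vs hole: step a little inside the ring and test whether
    # the distance field there is below the buffer width (inside the region).
    eps <- h / 20
    mx <- (ring[1, 1] + ring[2, 1]) / 2
    my <- (ring[1, 2] + ring[2, 2]) / 2
    ex <- ring[2, 1] - ring[1, 1]; ey <- ring[2, 2] - ring[1, 2]
    el <- sqrt(ex^2 + ey^2)
    if (el == 0) next
    nx <- -ey / el; ny <- ex / el
    p <- c(mx + eps * nx, my + eps * ny)
    if (!point_in_ring(p[1], p[2], ring)) {
      p <- c(mx - eps * nx, my - eps * ny)
    }
    d <- min_dist_to_segments(p[1], p[2], segs)
    sgn <- if (d < width) 1L else -1L
    rings[[length(rings) + 1L]] <- ring
    sign <- c(sign, sgn)
  }
  area <- 0
  if (length(rings)) {
    area <- sum(vapply(rings, function(r) abs(ring_signed_area(r)),
                       numeric(1)) * sign)
  }
  list(rings = rings, ring_sign = sign, area = max(area, 0), resolution = h)
}

# Regular polygon approximation of a circle (for GeoJSON export of the
# comparison buffer).
circle_ring <- function(center, radius, n = 1440) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
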