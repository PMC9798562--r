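# Internal 2-D polyline primitives. Traces are n x 2 double matrices in
# micrometres, ordered from the iris recess outward (anteriorly along the
# cornea, toward the pupil along the iris).

as_trace <- function(x, name = "trace") {
  if (is.matrix(x)) {
    m <- x
  } else if (is.list(x)) {
    m <- do.call(rbind, lapply(x, as.numeric))
  } else {
    m <- matrix(as.numeric(x), ncol = 2)
  }
  storage.mode(m) <- "double"
  if (ncol(m) != 2 || !all(is.finite(m))) {
    ag_stop(sprintf("%s must be a finite n x 2 point matrix", name), "bad-trace")
  }
  m
}

trace_cumarc <- function(pts) {
  n <- nrow(pts)
  if (n < 2) return(0)
  d <- sqrt((pts[-1, 1] - pts[-n, 1])^2 + (pts[-1, 2] - pts[-n, 2])^2)
  c(0, cumsum(d))
}

# Point at cumulative arc length s (clamped to the trace ends).
trace_point_at_arc <- function(pts, cum, s) {
  n <- nrow(pts)
  if (s <= 0) return(pts[1, ])
  if (s >= cum[n]) return(pts[n, ])
  i <- findInterval(s, cum, rightmost.closed = TRUE)
  i <- min(max(i, 1L), n - 1L)
  seg <- cum[i + 1L] - cum[i]
  t <- if (seg > 0) (s - cum[i]) / seg else 0
  pts[i, ] * (1 - t) + pts[i + 1L, ] * t
}

# Orthogonal projection of a point onto the polyline: distance, arc-length
# coordinate of the foot, and the foot itself.
trace_project <- function(pts, cum, p) {
  n <- nrow(pts)
  ax <- pts[-n, 1]; ay <- pts[-n, 2]
  bx <- pts[-1, 1]; by <- pts[-1, 2]
  abx <- bx - ax; aby <- by - ay
  len2 <- abx * abx + aby * aby
  t <- ((p[1] - ax) * abx + (p[2] - ay) * aby) / pmax(len2, 1e-300)
  t <- pmin(1, pmax(0, t))
  fx <- ax + t * abx; fy <- ay + t * aby
  d2 <- (p[1] - fx)^2 + (p[2] - fy)^2
  i <- which.min(d2)
  list(
    dist = sqrt(d2[i]),
    arc = cum[i] + t[i] * sqrt(len2[i]),
    point = c(fx[i], fy[i])
  )
}

# Sub-polyline between arc lengths s0 and s1, with interpolated end vertices.
trace_clip <- function(pts, cum, s0, s1) {
  total <- cum[length(cum)]
  s0 <- max(s0, 0); s1 <- min(s1, total)
  if (s1 - s0 <= 1e-12) return(NULL)
  inner <- which(cum > s0 & cum < s1)
  rbind(
    trace_point_at_arc(pts, cum, s0),
    pts[inner, , drop = FALSE],
    trace_point_at_arc(pts, cum, s1)
  )
}

# Minimum distance from each point of P (m x 2) to the polyline `pts`.
dist_points_to_polyline <- function(P, pts) {
  n <- nrow(pts); m <- nrow(P)
  ax <- pts[-n, 1]; ay <- pts[-n, 2]
  abx <- pts[-1, 1] - ax; aby <- pts[-1, 2] - ay
  len2 <- pmax(abx * abx + aby * aby, 1e-300)
  k <- n - 1L
  apx <- outer(P[, 1], ax, "-")
  apy <- outer(P[, 2], ay, "-")
  ABx <- matrix(abx, m, k, byrow = TRUE)
  ABy <- matrix(aby, m, k, byrow = TRUE)
  t <- (apx * ABx + apy * ABy) / matrix(len2, m, k, byrow = TRUE)
  t[t < 0] <- 0; t[t > 1] <- 1
  dx <- apx - t * ABx
  dy <- apy - t * ABy
  sqrt(apply(dx * dx + dy * dy, 1, min))
}

# Minimum distance between two polylines (vertex-to-segment, both directions;
# exact for the vertex-sampled boundaries used here).
polyline_min_dist <- function(A, B) {
  min(
    min(dist_points_to_polyline(A, B)),
    min(dist_points_to_polyline(B, A))
  )
}

# Signed clearance of each point of P from the polyline `pts`: unsigned
# minimum distance with the sign of the cross product of the nearest segment
# direction with the point offset (which side of the boundary the point is
# on). Points exactly on the boundary get 0.
signed_clearance <- function(P, pts) {
  n <- nrow(pts); m <- nrow(P)
  ax <- pts[-n, 1]; ay <- pts[-n, 2]
  abx <- pts[-1, 1] - ax; aby <- pts[-1, 2] - ay
  len2 <- pmax(abx * abx + aby * aby, 1e-300)
  k <- n - 1L
  apx <- outer(P[, 1], ax, "-")
  apy <- outer(P[, 2], ay, "-")
  ABx <- matrix(abx, m, k, byrow = TRUE)
  ABy <- matrix(aby, m, k, byrow = TRUE)
  t <- (apx * ABx + apy * ABy) / matrix(len2, m, k, byrow = TRUE)
  t[t < 0] <- 0; t[t > 1] <- 1
  dx <- apx - t * ABx
  dy <- apy - t * ABy
  d2 <- dx * dx + dy * dy
  j <- max.col(-d2, ties.method = "first")
  i <- seq_len(m)
  d <- sqrt(d2[cbind(i, j)])
  side <- sign(abx[j] * (P[, 2] - ay[j]) - aby[j] * (P[, 1] - ax[j]))
  d * side
}

# Crossings of the polyline with the line {X : (X - p0) . d = 0}.
# Returns crossing points and their arc-length coordinates.
trace_line_crossings <- function(pts, cum, p0, d) {
  f <- (pts[, 1] - p0[1]) * d[1] + (pts[, 2] - p0[2]) * d[2]
  n <- length(f)
  lo <- f[-n]; hi <- f[-1]
  idx <- which((lo <= 0 & hi >= 0 | lo >= 0 & hi <= 0) & (lo != 0 | hi != 0))
  if (length(idx) == 0) {
    return(list(points = matrix(numeric(0), 0, 2), arc = numeric(0)))
  }
  t <- lo[idx] / (lo[idx] - hi[idx])
  px <- pts[idx, 1] + t * (pts[idx + 1L, 1] - pts[idx, 1])
  py <- pts[idx, 2] + t * (pts[idx + 1L, 2] - pts[idx, 2])
  seg <- cum[idx + 1L] - cum[idx]
  list(points = cbind(px, py), arc = cum[idx] + t * seg)
}
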