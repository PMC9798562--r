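# Synthetic geometry used across the suite.

# Straight-armed wedge: cornea along +x from the recess at the origin, iris
# at `theta_deg` below it, spur at the recess (so the TM point sits 750 um
# along the cornea). `offset` shifts the whole iris down in parallel.
wedge_scan <- function(theta_deg, n = 120, len = 3000, offset = 0,
                       thickness = 450) {
  t <- seq(0, len, length.out = n)
  th <- -theta_deg * pi / 180
  iris <- cbind(t * cos(th), t * sin(th) - offset)
  angle_scan(
    quadrant = "temporal",
    cornea_inner = cbind(t, 0),
    iris_anterior = iris,
    iris_posterior = cbind(iris[, 1], iris[, 2] - thickness),
    scleral_spur = c(0, 0),
    iris_recess = c(0, 0),
    validate = FALSE
  )
}

# Quarter circle of radius r centred at (0, r), starting at the origin and
# sweeping toward +x; arc length from the start is r * phi.
quarter_circle <- function(n, r = 1000) {
  phi <- seq(0, pi / 2, length.out = n)
  cbind(r * sin(phi), r * (1 - cos(phi)))
}

rotation_matrix <- function(a) {
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# Rigid motion (+ optional uniform scale) applied to every coordinate of a
# scan; rebuilds the object so cached arc lengths stay consistent.
transform_scan <- function(scan, angle = 0, shift = c(0, 0), scale = 1) {
  R <- rotation_matrix(angle)
  tp <- function(m) scale * (m %*% t(R)) + matrix(shift, nrow(m), 2, byrow = TRUE)
  tv <- function(p) as.vector(scale * (R %*% p) + shift)
  angle_scan(
    quadrant = scan$quadrant,
    cornea_inner = tp(scan$cornea_inner),
    iris_anterior = tp(scan$iris_anterior),
    iris_posterior = if (!is.null(scan$iris_posterior)) tp(scan$iris_posterior),
    scleral_spur = tv(scan$scleral_spur),
    iris_recess = tv(scan$iris_recess),
    gradable = scan$gradable,
    validate = FALSE
  )
}

# Brute-force minimum vertex-pair distance between two traces restricted to
# a window of arc length, used as the apposition oracle.
brute_min_dist <- function(a, b, window) {
  ca <- c(0, cumsum(sqrt(rowSums(diff(a)^2))))
  cb <- c(0, cumsum(sqrt(rowSums(diff(b)^2))))
  a <- a[ca <= window, , drop = FALSE]
  b <- b[cb <= window, , drop = FALSE]
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(min(d2))
}
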