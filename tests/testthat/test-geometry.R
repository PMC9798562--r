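test_that("arc_point walks polyline arc length with interpolation", {
  straight <- cbind(c(0, 2000), c(0, 0))
  expect_equal(arc_point(straight, c(0, 0), 750), c(750, 0))

  elbow <- rbind(c(0, 0), c(500, 0), c(500, 500))
  expect_equal(arc_point(elbow, c(0, 0), 750), c(500, 250))

  # origin off the trace start: distance is measured from its projection
  expect_equal(arc_point(straight, c(100, 20), 500), c(600, 0))

  expect_error(arc_point(straight, c(0, 0), 5000), class = "trace-too-short")
  expect_error(arc_point(straight, c(0, 300), 100), class = "landmark-off-trace")
})

test_that("arc_point converges to the analytic circle oracle", {
  # central angle phi = s / r, so 750 um of arc sits at phi = 0.75 rad
  oracle <- c(1000 * sin(0.75), 1000 * (1 - cos(0.75)))
  p600 <- arc_point(quarter_circle(600), c(0, 0), 750)
  expect_lt(sqrt(sum((p600 - oracle)^2)), 1)
  err <- vapply(c(50, 200, 800), function(n) {
    sqrt(sum((arc_point(quarter_circle(n), c(0, 0), 750) - oracle)^2))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("TIA750 and AOD750 match closed forms on straight wedges", {
  expect_equal(compute_tia750(wedge_scan(20)), 20, tolerance = 1e-6)
  expect_equal(compute_tia750(wedge_scan(12)), 12, tolerance = 1e-6)
  for (theta in c(5, 12, 25, 38)) {
    expect_equal(compute_aod750(wedge_scan(theta)), 750 * tan(theta * pi / 180),
                 tolerance = 1e-6)
  }
})

test_that("AOD750 handles apposition and parallel-offset contact cases", {
  # iris coincident with the cornea over the first 800 um, then dropping away
  t <- seq(0, 3000, length.out = 200)
  y <- ifelse(t <= 800, 0, -(t - 800) * tan(30 * pi / 180))
  appos <- angle_scan("temporal", cbind(t, 0), cbind(t, y), cbind(t, y - 450),
                      scleral_spur = c(0, 0), iris_recess = c(0, 0),
                      validate = FALSE)
  expect_equal(compute_aod750(appos), 0)
  expect_true(detect_apposition(appos))
  expect_identical(classify_quadrant(appos)$angle_class, "closed")

  # parallel traces 30 um apart: AOD is the offset, not contact
  par30 <- wedge_scan(0.0001, offset = 30)
  expect_equal(compute_aod750(par30), 30, tolerance = 0.01)
  expect_false(detect_apposition(par30))
})

test_that("apposition detection respects tolerance and evaluation window", {
  expect_true(detect_apposition(wedge_scan(0.0001, offset = 5)))
  expect_false(detect_apposition(wedge_scan(20)))

  # contact only at arc length ~1200: outside the default 1000-um window
  t <- seq(0, 3000, length.out = 400)
  dip <- 30 - 30 * exp(-((t - 1200) / 40)^2)
  scan <- angle_scan("temporal", cbind(t, 0), cbind(t, -dip), NULL,
                     scleral_spur = c(0, 0), iris_recess = c(0, 0),
                     validate = FALSE)
  expect_false(detect_apposition(scan))
  expect_true(detect_apposition(scan, geometry_config(eval_window = 1400)))
  # agrees with the brute-force pairwise oracle in both windows
  expect_gt(brute_min_dist(scan$iris_anterior[scan$iris_cum >= 200, ],
                           scan$cornea_inner, 1000), 10)
})

test_that("preset classification distinguishes open, narrow, closed", {
  expect_identical(classify_quadrant(wedge_scan(20))$angle_class, "open")
  expect_identical(classify_quadrant(wedge_scan(8))$angle_class, "narrow")
  expect_identical(classify_quadrant(wedge_scan(12))$angle_class, "open")
  expect_identical(classify_quadrant(wedge_scan(11.99))$angle_class, "narrow")
  ung <- wedge_scan(20)
  ung$gradable <- FALSE
  expect_identical(classify_quadrant(ung)$angle_class, "ungradable")
})

test_that("classification is equivalent to thresholding TIA750 on wedges", {
  set.seed(421)
  theta <- runif(200, 0.5, 45)
  for (th in theta) {
    qa <- classify_quadrant(wedge_scan(th, n = 90))
    qualifying <- qa$angle_class %in% c("narrow", "closed")
    expect_identical(qualifying, qa$tia750 < 12)
    if (th > 4) expect_identical(qa$angle_class == "narrow", qa$tia750 < 12)
  }
})

test_that("metrics are rigid-motion invariant and scale equivariant", {
  set.seed(2)
  base <- list(wedge_scan(17), generate_scan(scan_recipe("bombe", target_tia = 24)))
  for (scan in base) {
    tia0 <- compute_tia750(scan)
    aod0 <- compute_aod750(scan)
    for (i in 1:10) {
      tr <- transform_scan(scan, angle = runif(1, -pi, pi),
                           shift = runif(2, -5000, 5000))
      expect_equal(compute_tia750(tr), tia0, tolerance = 1e-6)
      expect_equal(compute_aod750(tr), aod0, tolerance = 1e-6)
    }
    for (s in c(0.5, 2)) {
      sc <- transform_scan(scan, scale = s)
      cfg <- geometry_config(tm_offset = 750 * s, eval_window = 1000 * s,
                             apex_exclusion = 200 * s, apposition_tol = 10 * s,
                             landmark_tol = 50 * s)
      expect_equal(compute_tia750(sc, cfg), tia0, tolerance = 1e-6)
      expect_equal(compute_aod750(sc, cfg), s * aod0, tolerance = 1e-6)
    }
  }
})

test_that("AOD750 increases strictly with wedge angle", {
  aod <- vapply(seq(0.5, 40, by = 0.5), function(th) compute_aod750(wedge_scan(th)),
                numeric(1))
  expect_true(all(diff(aod) > 0))
})

test_that("TIA750 on a bombe iris agrees with a dense brute-force oracle", {
  r <- scan_recipe("bombe", target_tia = 20, n_vertices = 2000)
  scan <- generate_scan(r)
  tia <- compute_tia750(scan)

  # oracle: the same circular arc sampled at 1e4 points; perpendicular
  # intersection found by sign change of the plane function, refined linearly
  deg <- pi / 180
  a_c <- r$cornea_wedge / 2 * deg
  u_c <- c(cos(a_c), sin(a_c))
  P <- (100 + 750) * u_c
  a_i <- a_c - r$target_tia * deg
  u_i <- c(cos(a_i), sin(a_i))
  nrm <- c(-u_i[2], u_i[1])
  L <- r$iris_chord; s <- r$sagitta
  R <- (L^2 / 4 + s^2) / (2 * abs(s))
  C <- L / 2 * u_i + (abs(s) - R) * sign(s) * nrm
  phi0 <- atan2(-C[2], -C[1])
  mid <- L / 2 * u_i + s * nrm
  wrap <- function(x) atan2(sin(x), cos(x))
  dir <- sign(wrap(atan2(mid[2] - C[2], mid[1] - C[1]) - phi0))
  dense_phi <- phi0 + dir * seq(0, 1, length.out = 1e4) * (1000 / R)  # first 1000 um
  pts <- cbind(C[1] + R * cos(dense_phi), C[2] + R * sin(dense_phi))
  f <- (pts[, 1] - P[1]) * u_c[1] + (pts[, 2] - P[2]) * u_c[2]
  i <- which(f[-1e4] * f[-1] <= 0)
  expect_true(length(i) >= 1)
  tt <- f[i] / (f[i] - f[i + 1])
  Q <- pts[i, ] * (1 - tt) + pts[i + 1, ] * tt
  d2 <- (Q[1] - P[1])^2 + (Q[2] - P[2])^2
  if (length(i) > 1) {
    Qm <- rbind(pts[i, ] * (1 - tt) + pts[i + 1, ] * tt)
    d2 <- rowSums(sweep(Qm, 2, P)^2)
    Q <- Qm[which.min(d2), ]
  }
  oracle <- acos(sum(u_c * Q) / sqrt(sum(Q^2))) / deg
  expect_equal(tia, oracle, tolerance = 0.1)
})

test_that("degenerate and invalid scans error with classed conditions", {
  w <- wedge_scan(20)
  w$gradable <- FALSE
  expect_error(compute_tia750(w), class = "ungradable-scan")
  tiny <- angle_scan("temporal", cbind(c(0, 0.2, 0.4), c(0, 0, 0)),
                     cbind(c(0, 0.2, 0.4), c(0, -0.01, -0.02)), NULL,
                     scleral_spur = c(0, 0), iris_recess = c(0, 0),
                     validate = FALSE)
  expect_error(compute_tia750(tiny), class = "angleguard_error")
  expect_identical(classify_quadrant(tiny)$angle_class, "ungradable")
})

test_that("angle_scan validation reports landmark and trace problems", {
  t <- seq(0, 1000, length.out = 10)
  expect_error(
    angle_scan("temporal", cbind(t, 0), cbind(t, -t / 3), NULL,
               scleral_spur = c(0, 300), iris_recess = c(0, 0)),
    class = "invalid-scan"
  )
  dup <- rbind(c(0, 0), c(0, 0), c(10, 0), c(20, 0))
  p <- validate_angle_scan(
    angle_scan("temporal", dup, cbind(t, -t / 3), NULL,
               scleral_spur = c(0, 0), iris_recess = c(0, 0), validate = FALSE)
  )
  expect_true(any(grepl("strictly increasing", p)))
})
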