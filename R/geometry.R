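#' Geometry configuration for angle assessment
#'
#' Parameters of the preset-angle construction used to grade one quadrant of
#' an AS-OCT cross section. All lengths are micrometres, angles degrees.
#'
#' @param tm_offset arc length along the inner corneoscleral boundary from the
#'   scleral spur to the trabecular-meshwork reference point (default 750 um,
#'   the AOD750/TIA750 convention).
#' @param tia_threshold preset angle in degrees separating narrow from open
#'   (default 12). A quadrant is narrow when the peripheral iris falls
#'   strictly inside the preset wedge, equivalently TIA750 < 12 on straight
#'   iris contours.
#' @param apposition_tol maximum iris-cornea clearance (um) counted as
#'   appositional contact (default 10, below typical trace noise).
#' @param eval_window arc length (um) from the iris recess over which
#'   apposition and wedge membership are evaluated (default 1000, covering
#'   the trabecular meshwork with margin).
#' @param apex_exclusion arc length (um) from the recess excluded from
#'   apposition and wedge-membership checks (default 200). The two boundary
#'   traces meet at the recess, so the immediate apex is always in contact;
#'   this mirrors the blurred recess region a human grader ignores.
#' @param landmark_tol maximum distance (um) allowed between a landmark
#'   (scleral spur, iris recess) and the trace it belongs to (default 50).
#' @return a list of class `geometry_config`.
#' @export
geometry_config <- function(tm_offset = 750, tia_threshold = 12,
                            apposition_tol = 10, eval_window = 1000,
                            apex_exclusion = 200, landmark_tol = 50) {
  stopifnot(
    tm_offset > 0, apposition_tol > 0, eval_window > 0,
    apex_exclusion >= 0, apex_exclusion < eval_window, landmark_tol > 0
  )
  if (!(tia_threshold > 0 && tia_threshold < 90)) {
    ag_stop("tia_threshold must lie in (0, 90) degrees", "bad-config")
  }
  structure(
    list(
      tm_offset = tm_offset, tia_threshold = tia_threshold,
      apposition_tol = apposition_tol, eval_window = eval_window,
      apex_exclusion = apex_exclusion, landmark_tol = landmark_tol
    ),
    class = "geometry_config"
  )
}

#' Construct an angle scan (one quadrant's boundary traces)
#'
#' Bundles the per-quadrant boundary traces and landmarks of an AS-OCT
#' cross section. Traces are ordered point lists starting at the iris recess:
#' `cornea_inner` runs anteriorly along the inner corneoscleral boundary,
#' `iris_anterior` and `iris_posterior` run from the iris root toward the
#' pupil margin. Coordinates are multiplied by `pixel_scale` at construction
#' so all downstream geometry works in micrometres.
#'
#' @param quadrant one of `"temporal"`, `"nasal"`, `"superior"`, `"inferior"`.
#' @param cornea_inner,iris_anterior n x 2 point matrices (or lists of
#'   2-vectors).
#' @param iris_posterior optional posterior iris trace (needed for thickness,
#'   hence for the thick-peripheral configuration flag).
#' @param scleral_spur,iris_recess landmark points (length-2 numeric).
#' @param pixel_scale micrometres per coordinate unit (1 when the traces are
#'   already in um).
#' @param gradable logical image-quality flag; ungradable scans classify as
#'   `"ungradable"` without touching the geometry.
#' @param validate run [validate_angle_scan()] and stop on problems.
#' @return object of class `angle_scan`.
#' @export
angle_scan <- function(quadrant, cornea_inner, iris_anterior,
                       iris_posterior = NULL, scleral_spur, iris_recess,
                       pixel_scale = 1, gradable = TRUE, validate = TRUE) {
  quadrant <- match.arg(quadrant, c("temporal", "nasal", "superior", "inferior"))
  stopifnot(is.numeric(pixel_scale), pixel_scale > 0)
  sc <- function(m) as_trace(m) * pixel_scale
  scan <- structure(
    list(
      quadrant = quadrant,
      cornea_inner = sc(cornea_inner),
      iris_anterior = sc(iris_anterior),
      iris_posterior = if (!is.null(iris_posterior)) sc(iris_posterior),
      scleral_spur = as.numeric(scleral_spur) * pixel_scale,
      iris_recess = as.numeric(iris_recess) * pixel_scale,
      pixel_scale = pixel_scale,
      gradable = isTRUE(gradable)
    ),
    class = "angle_scan"
  )
  scan$cornea_cum <- trace_cumarc(scan$cornea_inner)
  scan$iris_cum <- trace_cumarc(scan$iris_anterior)
  if (validate) {
    problems <- validate_angle_scan(scan)
    if (length(problems)) {
      ag_stop(paste0("invalid angle_scan: ", paste(problems, collapse = "; ")),
              "invalid-scan")
    }
  }
  scan
}

#' Validate an angle scan against its structural invariants
#'
#' Checks trace lengths, strictly increasing arc-length parameterisation,
#' and landmark-trace consistency (spur on the cornea, recess at the start of
#' both cornea and iris traces, within `landmark_tol`).
#'
#' @param scan an `angle_scan`.
#' @param landmark_tol tolerance in micrometres (default 50).
#' @return character vector of problems; empty when the scan is valid.
#' @export
validate_angle_scan <- function(scan, landmark_tol = 50) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  check_trace <- function(pts, name) {
    if (is.null(pts)) return(invisible())
    if (nrow(pts) < 3) note(sprintf("%s: fewer than 3 points", name))
    if (nrow(pts) >= 2) {
      d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
      if (any(d <= 0)) note(sprintf("%s: arc length not strictly increasing", name))
    }
  }
  check_trace(scan$cornea_inner, "cornea_inner")
  check_trace(scan$iris_anterior, "iris_anterior")
  check_trace(scan$iris_posterior, "iris_posterior")
  if (!is_point(scan$scleral_spur)) note("scleral_spur: not a finite 2-D point")
  if (!is_point(scan$iris_recess)) note("iris_recess: not a finite 2-D point")
  if (!length(problems)) {
    pr <- trace_project(scan$cornea_inner, scan$cornea_cum, scan$scleral_spur)
    if (pr$dist > landmark_tol) {
      note(sprintf("scleral_spur: %.1f um off cornea_inner (tol %g)", pr$dist, landmark_tol))
    }
    d1 <- sqrt(sum((scan$iris_recess - scan$cornea_inner[1, ])^2))
    d2 <- sqrt(sum((scan$iris_recess - scan$iris_anterior[1, ])^2))
    if (d1 > landmark_tol) {
      note(sprintf("iris_recess: %.1f um from cornea_inner start (tol %g)", d1, landmark_tol))
    }
    if (d2 > landmark_tol) {
      note(sprintf("iris_recess: %.1f um from iris_anterior start (tol %g)", d2, landmark_tol))
    }
  }
  problems
}

#' Point at a given arc length along a trace
#'
#' Projects `origin` onto the trace and walks `distance` micrometres of
#' cumulative polyline arc length in the anterior direction (increasing trace
#' order, away from the recess), interpolating linearly within segments. This
#' is how the trabecular-meshwork reference point "750 um from the scleral
#' spur" is located on the inner corneoscleral boundary.
#'
#' @param trace n x 2 point matrix.
#' @param origin length-2 point lying on (or within `landmark_tol` of) the
#'   trace.
#' @param distance positive arc length in micrometres.
#' @param landmark_tol maximum allowed origin-to-trace distance (default 50).
#' @return length-2 numeric point.
#' @export
arc_point <- function(trace, origin, distance, landmark_tol = 50) {
  pts <- as_trace(trace)
  if (nrow(pts) < 2) ag_stop("trace has fewer than 2 points", "bad-trace")
  if (!is.numeric(distance) || length(distance) != 1 || distance <= 0) {
    ag_stop("distance must be a positive scalar", "bad-distance")
  }
  cum <- trace_cumarc(pts)
  pr <- trace_project(pts, cum, as.numeric(origin))
  if (pr$dist > landmark_tol) {
    ag_stop(sprintf("origin is %.1f um from the trace (tol %g)", pr$dist, landmark_tol),
            "landmark-off-trace")
  }
  s <- pr$arc + distance
  if (s > cum[length(cum)] + 1e-9) {
    ag_stop(sprintf("trace ends %.1f um short of the requested point",
                    s - cum[length(cum)]), "trace-too-short")
  }
  trace_point_at_arc(pts, cum, s)
}

# TM reference point P and the unit direction of the apex arm V -> P.
tm_arm <- function(scan, config) {
  V <- scan$iris_recess
  P <- arc_point(scan$cornea_inner, scan$scleral_spur, config$tm_offset,
                 config$landmark_tol)
  d <- P - V
  nd <- sqrt(sum(d * d))
  if (nd < 1) ag_stop("apex coincides with the TM point", "degenerate-angle")
  list(V = V, P = P, d = d / nd)
}

# Point Q where the line through P perpendicular to the arm V -> P meets the
# anterior iris surface (restricted to `eval_window` of arc length from the
# recess); falls back to the windowed iris point nearest to P.
iris_arm_point <- function(scan, P, d, config) {
  pts <- scan$iris_anterior
  cum <- scan$iris_cum
  cr <- trace_line_crossings(pts, cum, P, d)
  keep <- which(cr$arc <= config$eval_window)
  if (length(keep)) {
    dx <- cr$points[keep, 1] - P[1]
    dy <- cr$points[keep, 2] - P[2]
    i <- which.min(dx * dx + dy * dy)
    list(Q = cr$points[keep[i], ], crossing = TRUE)
  } else {
    win <- trace_clip(pts, cum, 0, config$eval_window)
    if (is.null(win)) ag_stop("empty iris window", "degenerate-angle")
    pr <- trace_project(win, trace_cumarc(win), P)
    list(Q = pr$point, crossing = FALSE)
  }
}

#' Trabecular-iris angle at 750 um (TIA750)
#'
#' Angle in degrees at the iris recess between the arm through the
#' trabecular-meshwork point (`tm_offset` of arc length anterior to the
#' scleral spur on the inner corneoscleral boundary) and the arm through the
#' point where the perpendicular to the first arm at the TM point meets the
#' anterior iris surface.
#'
#' @param scan an [angle_scan()].
#' @param config a [geometry_config()].
#' @return angle in degrees (non-negative).
#' @export
compute_tia750 <- function(scan, config = geometry_config()) {
  if (!scan$gradable) ag_stop("scan is not gradable", "ungradable-scan")
  arm <- tm_arm(scan, config)
  Q <- iris_arm_point(scan, arm$P, arm$d, config)$Q
  q <- Q - arm$V
  nq <- sqrt(sum(q * q))
  if (nq < 1) ag_stop("apex coincides with the iris arm point", "degenerate-angle")
  acos(min(1, max(-1, sum(arm$d * q) / nq))) * 180 / pi
}

#' Angle opening distance at 750 um (AOD750)
#'
#' Length of the perpendicular segment from the trabecular-meshwork reference
#' point to the anterior iris surface, measured perpendicular to the apex arm.
#' Returns 0 when the iris is appositional at the TM point (clearance within
#' `apposition_tol`).
#'
#' @inheritParams compute_tia750
#' @return distance in micrometres (non-negative).
#' @export
compute_aod750 <- function(scan, config = geometry_config()) {
  if (!scan$gradable) ag_stop("scan is not gradable", "ungradable-scan")
  arm <- tm_arm(scan, config)
  win <- trace_clip(scan$iris_anterior, scan$iris_cum, 0, config$eval_window)
  if (!is.null(win)) {
    pr <- trace_project(win, trace_cumarc(win), arm$P)
    if (pr$dist <= config$apposition_tol) return(0)
  }
  res <- iris_arm_point(scan, arm$P, arm$d, config)
  if (!res$crossing) {
    ag_stop("perpendicular at the TM point does not meet the iris within the window",
            "aod-undefined")
  }
  sqrt(sum((res$Q - arm$P)^2))
}

#' Detect iridotrabecular apposition
#'
#' TRUE when the minimum clearance between the anterior iris surface and the
#' inner corneoscleral boundary, both restricted to `eval_window` of arc
#' length from the recess (and excluding the first `apex_exclusion`
#' micrometres of iris, where the traces meet by construction), is at most
#' `apposition_tol`. Clearance is signed: iris points lying on the anterior
#' (cornea) side of the boundary — through or past it — count as contact,
#' so an iris pressed onto the trabecular meshwork is closed no matter how
#' the traces interleave.
#'
#' @inheritParams compute_tia750
#' @return logical.
#' @export
detect_apposition <- function(scan, config = geometry_config()) {
  if (!scan$gradable) ag_stop("scan is not gradable", "ungradable-scan")
  cor <- trace_clip(scan$cornea_inner, scan$cornea_cum, 0, config$eval_window)
  keep <- which(scan$iris_cum >= config$apex_exclusion &
                  scan$iris_cum <= config$eval_window)
  if (is.null(cor) || length(keep) == 0) return(FALSE)
  # the pupil-margin end of the iris fixes the posterior side of the cornea
  iri <- scan$iris_anterior[c(keep, nrow(scan$iris_anterior)), , drop = FALSE]
  sc <- signed_clearance(iri, cor)
  ref <- sc[length(sc)]
  sgn <- if (ref < 0) -1 else 1
  min(sgn * sc[-length(sc)]) <= config$apposition_tol
}

#' Classify one quadrant with the preset-angle rule
#'
#' Reproduces the screening read of one AS-OCT quadrant: `closed` when the
#' peripheral iris and trabecular meshwork are appositional; otherwise one arm
#' of a preset `tia_threshold`-degree angle is laid from the recess through
#' the TM point and the quadrant is `narrow` when any windowed anterior-iris
#' point falls strictly inside the wedge (angular coordinate from the TM arm,
#' measured toward the iris, strictly below the threshold), `open` otherwise.
#' Geometry failures downgrade the quadrant to `ungradable` rather than
#' raising, matching the exclusion of poor-quality images.
#'
#' @inheritParams compute_tia750
#' @param metrics also compute `tia750` / `aod750` (set `FALSE` for speed in
#'   large simulations; the class itself never needs them).
#' @return a `quadrant_assessment` list with fields `quadrant`, `tia750`,
#'   `aod750`, `angle_class` (`"open"`, `"narrow"`, `"closed"`,
#'   `"ungradable"`), `iris_configuration` (filled by the grading layer),
#'   `metrics_valid` and `reason`.
#' @export
classify_quadrant <- function(scan, config = geometry_config(), metrics = TRUE) {
  qa <- structure(
    list(quadrant = scan$quadrant, tia750 = NA_real_, aod750 = NA_real_,
         angle_class = "ungradable", iris_configuration = NA_character_,
         metrics_valid = FALSE, reason = NA_character_),
    class = "quadrant_assessment"
  )
  if (!scan$gradable) {
    qa$reason <- "image-quality"
    return(qa)
  }
  cls <- tryCatch({
    if (detect_apposition(scan, config)) {
      "closed"
    } else {
      arm <- tm_arm(scan, config)
      pts <- scan$iris_anterior
      keep <- which(scan$iris_cum >= config$apex_exclusion &
                      scan$iris_cum <= config$eval_window)
      ux <- pts[keep, 1] - arm$V[1]
      uy <- pts[keep, 2] - arm$V[2]
      far <- ux * ux + uy * uy >= 1
      ux <- ux[far]; uy <- uy[far]
      if (!length(ux)) ag_stop("no evaluable iris points", "degenerate-angle")
      cross <- arm$d[1] * uy - arm$d[2] * ux
      dot <- arm$d[1] * ux + arm$d[2] * uy
      # the iris side of the TM arm is fixed by the pupil-margin end of the
      # iris trace (robust when a deformed periphery rises past the arm)
      pe <- scan$iris_anterior[nrow(scan$iris_anterior), ] - arm$V
      side <- sign(arm$d[1] * pe[2] - arm$d[2] * pe[1])
      if (side == 0) side <- 1
      ang <- atan2(side * cross, dot) * 180 / pi
      # strictly inside the preset wedge: ties (within numerical precision)
      # classify as open
      if (any(ang < config$tia_threshold - 1e-9)) "narrow" else "open"
    }
  }, angleguard_error = function(e) {
    qa$reason <<- class(e)[1]
    "ungradable"
  })
  qa$angle_class <- cls
  if (metrics && cls != "ungradable") {
    qa$tia750 <- tryCatch(compute_tia750(scan, config),
                          angleguard_error = function(e) NA_real_)
    qa$aod750 <- tryCatch(compute_aod750(scan, config),
                          angleguard_error = function(e) NA_real_)
    qa$metrics_valid <- !is.na(qa$tia750) && !is.na(qa$aod750)
  }
  qa
}
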