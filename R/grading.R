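#' Iris shape thresholds
#'
#' Operational cut-offs turning the visual iris-configuration taxonomy
#' (flat, bowing, bombe, thick peripheral, mixed) into measurable flags.
#' The taxonomy itself is qualitative; these defaults are chosen so the
#' synthetic generator presets are unambiguous, and are fully configurable.
#'
#' @param curvature_cut minimum absolute chord deviation (um) of the anterior
#'   iris surface counted as bowing/bombe (default 80).
#' @param thickness_cut iris thickness (um) above which the periphery counts
#'   as thick (default 600).
#' @param thickness_offset arc length (um) from the iris root at which
#'   thickness is measured (default 750).
#' @return list of class `shape_thresholds`.
#' @export
shape_thresholds <- function(curvature_cut = 80, thickness_cut = 600,
                             thickness_offset = 750) {
  stopifnot(curvature_cut > 0, thickness_cut > 0, thickness_offset > 0)
  structure(
    list(curvature_cut = curvature_cut, thickness_cut = thickness_cut,
         thickness_offset = thickness_offset),
    class = "shape_thresholds"
  )
}

iris_configurations <- c("flat", "bowing", "bombe", "thick_peripheral", "mixed")

# Signed extremal deviation of the anterior iris surface from its chord,
# positive toward the cornea: the bombe/bowing discriminator.
iris_chord_deviation <- function(scan) {
  pts <- scan$iris_anterior
  n <- nrow(pts)
  A <- pts[1, ]; B <- pts[n, ]
  ch <- B - A
  L <- sqrt(sum(ch * ch))
  if (L < 1e-9) ag_stop("degenerate iris chord", "degenerate-angle")
  nrm <- c(-ch[2], ch[1]) / L
  dev <- (pts[, 1] - A[1]) * nrm[1] + (pts[, 2] - A[2]) * nrm[2]
  cor_dev <- mean((scan$cornea_inner[, 1] - A[1]) * nrm[1] +
                    (scan$cornea_inner[, 2] - A[2]) * nrm[2])
  s <- if (cor_dev < 0) -1 else 1
  dev <- dev * s
  dev[which.max(abs(dev))]
}

# Iris thickness at `thickness_offset` from the root, measured perpendicular
# to the anterior surface; NA when the posterior trace is missing.
iris_thickness <- function(scan, thresholds = shape_thresholds()) {
  if (is.null(scan$iris_posterior)) return(NA_real_)
  pts <- scan$iris_anterior
  cum <- scan$iris_cum
  off <- min(thresholds$thickness_offset, cum[length(cum)] * 0.9)
  A <- trace_point_at_arc(pts, cum, off)
  # tangent over a +/-100 um neighborhood: a single noisy segment would tilt
  # the perpendicular and inflate the oblique crossing distance
  h <- min(100, off, cum[length(cum)] - off)
  tang <- trace_point_at_arc(pts, cum, off + h) - trace_point_at_arc(pts, cum, off - h)
  tang <- tang / sqrt(sum(tang * tang))
  post <- scan$iris_posterior
  cr <- trace_line_crossings(post, trace_cumarc(post), A, tang)
  if (nrow(cr$points)) {
    dx <- cr$points[, 1] - A[1]; dy <- cr$points[, 2] - A[2]
    sqrt(min(dx * dx + dy * dy))
  } else {
    trace_project(post, trace_cumarc(post), A)$dist
  }
}

#' Classify the iris configuration of one quadrant
#'
#' Measures the chord deviation `c` of the anterior iris surface (signed,
#' positive toward the cornea) and the peripheral thickness `t`, then flags
#' bombe (`c > curvature_cut`), bowing (`c < -curvature_cut`) and thick
#' peripheral iris (`t > thickness_cut`). Two or more flags give `mixed`
#' (a single contour showing two mechanisms, e.g. bombe plus thick
#' periphery), exactly one gives that label, none gives `flat`. A missing
#' posterior trace makes thickness untestable; classification then proceeds
#' on curvature alone with a warning.
#'
#' @param scan an [angle_scan()] with both iris surfaces.
#' @param thresholds a [shape_thresholds()].
#' @return one of `"flat"`, `"bowing"`, `"bombe"`, `"thick_peripheral"`,
#'   `"mixed"`.
#' @export
classify_iris_configuration <- function(scan, thresholds = shape_thresholds()) {
  if (!scan$gradable) ag_stop("scan is not gradable", "ungradable-scan")
  cdev <- iris_chord_deviation(scan)
  thick <- iris_thickness(scan, thresholds)
  if (is.na(thick)) {
    warning("iris_posterior missing: thickness untestable, classifying on curvature only",
            call. = FALSE)
    thick <- -Inf
  }
  flags <- c(
    bombe = cdev > thresholds$curvature_cut,
    bowing = cdev < -thresholds$curvature_cut,
    thick_peripheral = thick > thresholds$thickness_cut
  )
  k <- sum(flags)
  if (k >= 2) "mixed" else if (k == 1) names(flags)[flags] else "flat"
}

#' Eye-level iris configuration from quadrant labels
#'
#' The eye is `mixed` when two or more distinct configurations are seen
#' across its gradable quadrants, or when any quadrant is itself mixed;
#' otherwise the unanimous quadrant label carries over. Ungradable quadrants
#' (`NA`) are ignored.
#'
#' @param quadrant_labels character vector of per-quadrant configurations
#'   (`NA` for ungradable quadrants).
#' @return a single configuration label.
#' @export
eye_configuration <- function(quadrant_labels) {
  lab <- quadrant_labels[!is.na(quadrant_labels)]
  if (!length(lab)) ag_stop("no gradable quadrant configuration", "no-configuration")
  bad <- setdiff(unique(lab), iris_configurations)
  if (length(bad)) {
    ag_stop(paste0("unknown configuration label: ", paste(bad, collapse = ", ")),
            "bad-label")
  }
  if (any(lab == "mixed") || length(unique(lab)) >= 2) "mixed" else lab[1]
}

#' Aggregate four quadrant assessments into an eye-level HRAC call
#'
#' An eye is at high risk of angle closure (HRAC) when at least 3 of its 4
#' quadrants are narrow or closed. The count is absolute: with fewer than 3
#' gradable quadrants and fewer than 3 qualifying ones the eye is
#' ungradable-for-HRAC (`hrac = NA`), distinct from `hrac = FALSE`.
#' Appositional closure is flagged when any quadrant is closed.
#'
#' @param assessments list of 4 `quadrant_assessment` objects (or any list
#'   with an `angle_class` field each).
#' @param eye `"OD"` or `"OS"`.
#' @return an `eye_assessment` list with `eye`, `quadrants`, `classes`,
#'   `n_gradable`, `n_qualifying`, `hrac`, `appositional_closure`.
#' @export
aggregate_hrac <- function(assessments, eye = "OD") {
  cls <- vapply(assessments, function(a) a$angle_class, character(1))
  qual <- sum(cls %in% c("narrow", "closed"))
  ng <- sum(cls != "ungradable")
  hrac <- if (qual >= 3) TRUE else if (ng < 3) NA else FALSE
  structure(
    list(
      eye = eye, quadrants = assessments, classes = cls,
      n_gradable = ng, n_qualifying = qual, hrac = hrac,
      appositional_closure = any(cls == "closed")
    ),
    class = "eye_assessment"
  )
}

#' Choose the analyzed eye for a participant
#'
#' The right eye is analyzed unless at least two of its quadrants are
#' unidentifiable, in which case the left eye is used; when both eyes fail
#' that rule the participant is ungradable (the bilateral poor-image
#' exclusion).
#'
#' @param od,os either an `eye_assessment` or the number of ungradable
#'   quadrants in that eye (0-4).
#' @return `"OD"`, `"OS"`, or `NA_character_` for participant-ungradable.
#' @export
select_eye <- function(od, os) {
  n_ungradable <- function(e) {
    if (is.numeric(e)) return(e)
    if (inherits(e, "eye_assessment")) return(4 - e$n_gradable)
    if (is.null(e)) return(4)
    ag_stop("eye must be an eye_assessment or an ungradable-quadrant count", "bad-eye")
  }
  if (n_ungradable(od) <= 1) "OD"
  else if (n_ungradable(os) <= 1) "OS"
  else NA_character_
}

#' Adjudicate two graders' labels, consulting a third on disagreement
#'
#' Agreement between the two primary graders stands; on disagreement the
#' third analyst's label decides by majority; a three-way split is flagged
#' `"unresolved"` for manual review.
#'
#' @param g1,g2 the two primary graders' labels.
#' @param g3 optional third analyst's label.
#' @return the adjudicated label (possibly `"unresolved"`).
#' @export
adjudicate <- function(g1, g2, g3 = NULL) {
  if (identical(g1, g2)) return(g1)
  if (is.null(g3)) {
    ag_stop("graders disagree and no third analyst label is available",
            "needs-third-grader")
  }
  if (identical(g3, g1)) g1
  else if (identical(g3, g2)) g2
  else "unresolved"
}

#' Calibrate the narrow-angle TIA threshold from gonioscopy-graded scans
#'
#' Given trabecular-iris angles measured on AS-OCT images whose quadrants
#' were graded Scheie N3 on gonioscopy (only the anterior third of the
#' trabecular meshwork visible), the screening threshold is the sample mean
#' rounded to the nearest whole degree; the unrounded mean and SD are
#' reported alongside.
#'
#' @param tia_values numeric vector of TIA values in degrees, each in (0, 90).
#' @return list with `threshold` (integer degrees), `mean`, `sd`, `n`, and a
#'   formatted `label` (`"mean +/- sd"`).
#' @export
calibrate_threshold <- function(tia_values) {
  if (!length(tia_values)) ag_stop("empty calibration set", "empty-calibration")
  if (!all(is.finite(tia_values)) || any(tia_values <= 0 | tia_values >= 90)) {
    ag_stop("calibration TIA values must lie in (0, 90) degrees", "bad-calibration")
  }
  m <- mean(tia_values)
  s <- stats::sd(tia_values)
  list(
    threshold = as.integer(round_half_up(m, 0)),
    mean = m, sd = s, n = length(tia_values),
    label = sprintf("%.1f ± %.1f", m, s)
  )
}

#' Synthetic gonioscopy calibration set
#'
#' Draws `n` TIA values from a normal model and affinely standardises them to
#' the requested sample mean and SD exactly, redrawing if any value leaves
#' (0, 90) degrees. Used to emulate the N3-graded calibration sample.
#'
#' @param n number of values (default 97).
#' @param mean,sd target sample moments in degrees (defaults 12.1 and 5.8).
#' @param seed optional RNG seed (caller's RNG state is preserved).
#' @return numeric vector of length `n` with exact sample mean and SD.
#' @export
synthetic_calibration_set <- function(n = 97, mean = 12.1, sd = 5.8, seed = NULL) {
  stopifnot(n >= 3, mean > 0, mean < 90, sd > 0)
  with_seed(seed, {
    for (i in 1:200) {
      x <- stats::rnorm(n, mean, sd)
      # resample individual values outside a safe band before standardising
      bad <- x < sd / 10 | x > 90 - sd / 10
      for (j in 1:100) {
        if (!any(bad)) break
        x[bad] <- stats::rnorm(sum(bad), mean, sd)
        bad <- x < sd / 10 | x > 90 - sd / 10
      }
      y <- mean + sd * (x - base::mean(x)) / stats::sd(x)
      if (all(y > 0 & y < 90)) return(y)
    }
    ag_stop("could not construct a calibration set inside (0, 90)", "bad-calibration")
  })
}
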