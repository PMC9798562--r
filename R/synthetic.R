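#' Recipe for one synthetic angle scan
#'
#' Parametric anterior-segment quadrant: a straight inner corneoscleral
#' boundary leaving the recess at half the `cornea_wedge` angle, and an
#' anterior iris surface modelled as a circular arc over a chord leaving the
#' recess such that the straight-chord trabecular-iris angle equals
#' `target_tia` before the sagitta deformation. The posterior surface is the
#' anterior one offset by `thickness` away from the cornea. This two-parameter
#' family (sagitta, thickness) spans the iris-configuration taxonomy: flat
#' (sagitta 0), bombe (+400 um toward the cornea), bowing (-300 um),
#' thick peripheral iris (700 um thickness) and their mixed combination.
#'
#' @param configuration one of `"flat"`, `"bowing"`, `"bombe"`,
#'   `"thick_peripheral"`, `"bombe_thick"`; presets `sagitta` / `thickness`
#'   when those are `NULL`.
#' @param target_tia straight-chord trabecular-iris angle in degrees,
#'   in (0, `cornea_wedge`).
#' @param cornea_wedge inclination budget of the quadrant in degrees
#'   (default 35); the cornea arm runs at half of it.
#' @param iris_chord chord length of the iris trace in um (default 3000).
#' @param sagitta signed mid-chord bulge in um, positive toward the cornea.
#' @param thickness iris thickness in um.
#' @param noise_sd per-vertex Gaussian perpendicular trace noise in um.
#' @param n_vertices vertices per trace (>= 50, default 200).
#' @param seed optional RNG seed for the noise (caller's state preserved).
#' @param quadrant quadrant label for the generated scan.
#' @param spur_offset arc length from the recess to the scleral spur along
#'   the cornea (default 100 um).
#' @return list of class `scan_recipe`.
#' @export
scan_recipe <- function(configuration = c("flat", "bowing", "bombe",
                                          "thick_peripheral", "bombe_thick"),
                        target_tia = 20, cornea_wedge = 35, iris_chord = 3000,
                        sagitta = NULL, thickness = NULL, noise_sd = 0,
                        n_vertices = 200, seed = NULL, quadrant = "temporal",
                        spur_offset = 100) {
  configuration <- match.arg(configuration)
  preset_s <- c(flat = 0, bowing = -300, bombe = 400,
                thick_peripheral = 0, bombe_thick = 400)
  preset_t <- c(flat = 450, bowing = 450, bombe = 450,
                thick_peripheral = 700, bombe_thick = 700)
  if (is.null(sagitta)) sagitta <- unname(preset_s[configuration])
  if (is.null(thickness)) thickness <- unname(preset_t[configuration])
  if (n_vertices < 50) ag_stop("n_vertices must be >= 50", "bad-recipe")
  if (abs(sagitta) >= iris_chord / 2) {
    ag_stop("|sagitta| must be below iris_chord / 2", "bad-recipe")
  }
  if (!(target_tia > 0 && target_tia < cornea_wedge)) {
    ag_stop("target_tia must lie in (0, cornea_wedge)", "bad-recipe")
  }
  if (noise_sd < 0 || thickness <= 0 || iris_chord <= 0 || spur_offset <= 0) {
    ag_stop("recipe lengths must be positive and noise_sd non-negative", "bad-recipe")
  }
  structure(
    list(configuration = configuration, target_tia = target_tia,
         cornea_wedge = cornea_wedge, iris_chord = iris_chord,
         sagitta = sagitta, thickness = thickness, noise_sd = noise_sd,
         n_vertices = as.integer(n_vertices), seed = seed,
         quadrant = quadrant, spur_offset = spur_offset),
    class = "scan_recipe"
  )
}

# Circular-arc vertices from (0,0) to L*u with signed sagitta s along nrm
# (unit normal toward the cornea). Returns vertices and the cornea-side unit
# normal at each vertex.
iris_arc_vertices <- function(L, u, nrm, s, k) {
  if (abs(s) < 1e-9) {
    tt <- seq(0, L, length.out = k)
    return(list(pts = cbind(tt * u[1], tt * u[2]),
                normal = matrix(nrm, k, 2, byrow = TRUE)))
  }
  R <- (L^2 / 4 + s^2) / (2 * abs(s))
  M <- L / 2 * u
  C <- M + (abs(s) - R) * sign(s) * nrm
  wrap <- function(x) atan2(sin(x), cos(x))
  thA <- atan2(-C[2], -C[1])
  thB <- atan2(L * u[2] - C[2], L * u[1] - C[1])
  mid <- M + s * nrm
  thM <- atan2(mid[2] - C[2], mid[1] - C[1])
  d1 <- wrap(thM - thA)
  d2 <- wrap(thB - thM)
  th <- thA + seq(0, 1, length.out = k) * (d1 + d2)
  pts <- cbind(C[1] + R * cos(th), C[2] + R * sin(th))
  normal <- sign(s) * (pts - matrix(C, k, 2, byrow = TRUE)) / R
  list(pts = pts, normal = normal)
}

#' Generate a synthetic angle scan from a recipe
#'
#' Realises the parametric quadrant geometry of a [scan_recipe()] as a valid
#' [angle_scan()]: recess at the origin, straight cornea arm, circular-arc
#' anterior iris with posterior offset, landmarks on-trace, and optional
#' i.i.d. Gaussian perpendicular vertex noise (the shared recess vertex is
#' left exact so the landmark invariants always hold). With a fixed seed the
#' output is bit-reproducible.
#'
#' @param recipe a [scan_recipe()] (or a list with the same fields).
#' @return an [angle_scan()].
#' @export
generate_scan <- function(recipe) {
  r <- recipe
  deg <- pi / 180
  a_c <- r$cornea_wedge / 2 * deg
  u_c <- c(cos(a_c), sin(a_c))
  n_c <- c(-u_c[2], u_c[1])
  k <- r$n_vertices
  cornea_len <- max(2500, r$spur_offset + 1800)
  tt <- seq(0, cornea_len, length.out = k)
  cornea <- cbind(tt * u_c[1], tt * u_c[2])

  a_i <- a_c - r$target_tia * deg
  u_i <- c(cos(a_i), sin(a_i))
  nrm <- c(-u_i[2], u_i[1])  # +90 deg, toward the cornea side
  arc <- iris_arc_vertices(r$iris_chord, u_i, nrm, r$sagitta, k)
  anterior <- arc$pts
  posterior <- anterior - r$thickness * arc$normal

  if (r$noise_sd > 0) {
    with_seed(r$seed, {
      jit <- function(pts, normal) {
        e <- stats::rnorm(nrow(pts), 0, r$noise_sd)
        e[1] <- 0  # keep the recess vertex exact
        pts + e * normal
      }
      anterior <- jit(anterior, arc$normal)
      posterior <- jit(posterior, arc$normal)
      cornea <- jit(cornea, matrix(n_c, k, 2, byrow = TRUE))
    })
  }

  angle_scan(
    quadrant = r$quadrant,
    cornea_inner = cornea,
    iris_anterior = anterior,
    iris_posterior = posterior,
    scleral_spur = r$spur_offset * u_c,
    iris_recess = c(0, 0),
    pixel_scale = 1,
    gradable = TRUE,
    validate = FALSE
  )
}

age_bands <- c("40-49", "50-59", "60-69", "70+")

#' Age band of a participant
#'
#' Decade bands 40-49, 50-59, 60-69 and 70+ used for stratified reporting.
#'
#' @param age numeric vector of ages in years.
#' @return factor with levels `"40-49"`, `"50-59"`, `"60-69"`, `"70+"`.
#' @export
age_band <- function(age) {
  cut(age, breaks = c(40, 50, 60, 70, Inf), right = FALSE, labels = age_bands)
}

#' Reference screening counts
#'
#' The stratified counts of the reference health-examination-center screening
#' study that this package's cohort tools reproduce: per gender-by-age-band
#' HRAC numerators and denominators (with the published gender and age
#' marginals), the iris-configuration distribution among eyes with and
#' without HRAC, and the exclusion-cascade counts of the 1282 enrolled
#' participants. These printed summaries are the fixed inputs of
#' [reference_cohort()] and the default [cohort_spec()].
#'
#' Note: the published male age-stratum denominators sum to 561 while the
#' male total is printed as 579 (overall 973 vs 991); the per-cell table
#' below reproduces the printed cells, and the marginals carry the printed
#' totals.
#'
#' @return list with `cells` (gender x age-band data frame with `numerator`,
#'   `denominator`), `age_totals`, `gender_totals`, `overall`,
#'   `configurations` (counts by HRAC status) and `exclusions` (named counts
#'   in precedence order) plus `n_enrolled`.
#' @export
reference_counts <- function() {
  cells <- data.frame(
    gender = rep(c("male", "female"), each = 4),
    age_band = rep(age_bands, 2),
    numerator = c(1, 6, 18, 7, 8, 16, 18, 4),
    denominator = c(165, 190, 186, 20, 148, 150, 98, 16),
    stringsAsFactors = FALSE
  )
  age_totals <- data.frame(
    age_band = age_bands,
    numerator = c(9, 22, 36, 11),
    denominator = c(313, 340, 284, 36),
    stringsAsFactors = FALSE
  )
  gender_totals <- data.frame(
    gender = c("male", "female"),
    numerator = c(32, 46),
    denominator = c(579, 412),
    stringsAsFactors = FALSE
  )
  configurations <- data.frame(
    configuration = c("flat", "bowing", "bombe", "thick_peripheral", "mixed"),
    hrac = c(0, 0, 19, 22, 37),
    non_hrac = c(666, 51, 15, 118, 63),
    stringsAsFactors = FALSE
  )
  exclusions <- c(
    poor_image = 80, low_pva = 93, high_iop = 17,
    glaucoma_suspect = 30, retinal_abnormal = 38, prior_surgery = 33
  )
  list(
    cells = cells, age_totals = age_totals, gender_totals = gender_totals,
    overall = c(numerator = 78, denominator = 991),
    configurations = configurations,
    exclusions = exclusions, n_enrolled = 1282
  )
}

#' Deterministic reference screening roster
#'
#' Builds, without any randomness, a roster of 1282 participant records whose
#' exclusion flags reproduce the reference exclusion counts exactly
#' (80 bilateral poor image, 93 low PVA, 17 high IOP, 30 glaucoma suspect,
#' 38 retinal abnormality, 33 prior surgery; 991 included), whose included
#' gender totals are 579 men and 412 women, and whose per-stratum HRAC labels
#' match the reference numerators. Because the published male age-stratum
#' denominators sum 18 short of the male total, the 18 unaccounted men are
#' placed in the 60-69 stratum; see `attr(x, "notes")`.
#'
#' Ages are spread evenly within bands (70+ capped at 84), included eyes get
#' normal screening measurements (PVA 6/6, IOP 16 mmHg), and HRAC eyes carry
#' an iris-configuration label drawn deterministically from the reference
#' configuration distribution.
#'
#' @return data frame of participant records (one row per participant) with
#'   columns `id`, `age`, `gender`, `pva_better_eye` (Snellen fraction),
#'   `iop_od`, `iop_os`, `fundus_glaucoma_suspect`, `fundus_other_abnormal`,
#'   `prior_ocular_surgery`, `bilateral_poor_image`, `hrac_label`,
#'   `configuration`.
#' @export
reference_cohort <- function() {
  ref <- reference_counts()
  cells <- ref$cells
  # 18 men unaccounted for by the printed male age strata -> 60-69 stratum
  cells$denominator[cells$gender == "male" & cells$age_band == "60-69"] <-
    cells$denominator[cells$gender == "male" & cells$age_band == "60-69"] + 18

  band_ages <- list(`40-49` = 40:49, `50-59` = 50:59, `60-69` = 60:69, `70+` = 70:84)

  inc <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    n <- cells$denominator[i]
    k <- cells$numerator[i]
    ages <- band_ages[[cells$age_band[i]]]
    data.frame(
      age = ages[(seq_len(n) - 1) %% length(ages) + 1],
      gender = cells$gender[i],
      hrac_label = c(rep(TRUE, k), rep(FALSE, n - k)),
      stringsAsFactors = FALSE
    )
  }))
  inc$pva_better_eye <- 1.0
  inc$iop_od <- 16; inc$iop_os <- 16
  inc$fundus_glaucoma_suspect <- FALSE
  inc$fundus_other_abnormal <- FALSE
  inc$prior_ocular_surgery <- FALSE
  inc$bilateral_poor_image <- FALSE

  # iris configurations: reference distribution, assigned deterministically
  cfg <- ref$configurations
  inc$configuration <- NA_character_
  inc$configuration[inc$hrac_label] <- rep(cfg$configuration, cfg$hrac)
  inc$configuration[!inc$hrac_label] <- rep(cfg$configuration, cfg$non_hrac)

  exc_reason <- rep(names(ref$exclusions), ref$exclusions)
  n_exc <- length(exc_reason)
  exc <- data.frame(
    age = 40 + (seq_len(n_exc) - 1) %% 45,
    gender = rep(c("male", "female"), length.out = n_exc),
    hrac_label = NA,
    pva_better_eye = ifelse(exc_reason == "low_pva", 6 / 18, 1.0),
    iop_od = ifelse(exc_reason == "high_iop", 26, 16),
    iop_os = 16,
    fundus_glaucoma_suspect = exc_reason == "glaucoma_suspect",
    fundus_other_abnormal = exc_reason == "retinal_abnormal",
    prior_ocular_surgery = exc_reason == "prior_surgery",
    bilateral_poor_image = exc_reason == "poor_image",
    configuration = NA_character_,
    stringsAsFactors = FALSE
  )

  roster <- rbind(inc, exc)
  roster <- cbind(id = sprintf("P%04d", seq_len(nrow(roster))), roster)
  rownames(roster) <- NULL
  attr(roster, "notes") <- paste(
    "Published male age-stratum denominators sum to 561, not the published",
    "male total of 579; the 18 unaccounted men are assigned to the 60-69",
    "male stratum. Published per-cell counts are otherwise honored."
  )
  roster
}

#' Specification of a simulated screening cohort
#'
#' Study conditions for [simulate_cohort()]. The defaults are the reference
#' screening study's conditions: per-stratum included sizes and HRAC
#' prevalences equal to the published gender-by-age cells, the published
#' exclusion counts on top, and iris-configuration mixes taken from the
#' published configuration distribution. Non-HRAC geometry draws only the
#' configurations compatible with keeping every quadrant clear of the preset
#' arm in this wedge model (flat, bowing, thick peripheral); see the methods
#' vignette.
#'
#' @param strata data frame with columns `gender`, `age_band`, `n`,
#'   `prevalence`.
#' @param exclusions named counts of excluded participants per reason,
#'   in precedence order.
#' @param hrac_config_prob,non_hrac_config_prob named probability weights for
#'   eye-level configuration labels.
#' @param narrow_tia_range,open_tia_range uniform TIA ranges (degrees) for
#'   qualifying and non-qualifying quadrants.
#' @param n_narrow_non_hrac_prob probabilities that a non-HRAC eye carries
#'   0, 1 or 2 qualifying quadrants.
#' @param noise_sd trace noise (um) for generated scans (default 0: the
#'   cohort simulation isolates sampling variability; noise robustness is
#'   characterised separately by the label-recovery experiments).
#' @param n_vertices vertices per generated trace (default 60).
#' @param seed RNG seed for the whole cohort draw.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(strata = NULL, exclusions = NULL,
                        hrac_config_prob = c(bombe = 19, thick_peripheral = 22, mixed = 37),
                        non_hrac_config_prob = c(flat = 666, bowing = 51, thick_peripheral = 118),
                        narrow_tia_range = c(5, 11), open_tia_range = c(15, 30),
                        n_narrow_non_hrac_prob = c(`0` = 0.85, `1` = 0.10, `2` = 0.05),
                        noise_sd = 0, n_vertices = 60, seed = NULL) {
  ref <- reference_counts()
  if (is.null(strata)) {
    strata <- ref$cells
    strata$n <- strata$denominator
    strata$prevalence <- strata$numerator / strata$denominator
    strata <- strata[c("gender", "age_band", "n", "prevalence")]
  }
  if (is.null(exclusions)) exclusions <- ref$exclusions
  stopifnot(
    all(c("gender", "age_band", "n", "prevalence") %in% names(strata)),
    all(strata$prevalence >= 0 & strata$prevalence <= 1),
    all(strata$n >= 0), all(exclusions >= 0)
  )
  structure(
    list(strata = strata, exclusions = exclusions,
         hrac_config_prob = hrac_config_prob,
         non_hrac_config_prob = non_hrac_config_prob,
         narrow_tia_range = narrow_tia_range, open_tia_range = open_tia_range,
         n_narrow_non_hrac_prob = n_narrow_non_hrac_prob,
         noise_sd = noise_sd, n_vertices = as.integer(n_vertices), seed = seed),
    class = "cohort_spec"
  )
}

quadrant_names <- c("temporal", "nasal", "superior", "inferior")

#' Simulate a screening cohort with per-eye scan recipes
#'
#' Samples a roster under a [cohort_spec()]: excluded participants carry the
#' spec's exclusion flags (fixed counts), included participants are drawn per
#' stratum with Bernoulli HRAC labels at the stratum prevalence, and each
#' included participant receives four right-eye quadrant recipes. HRAC eyes
#' get 3 or 4 qualifying quadrants (50/50) with TIA uniform in the narrow
#' range; non-HRAC eyes get 0-2 qualifying quadrants with the remaining
#' quadrants uniform in the open range. Eye-level configuration labels are
#' drawn from the spec's mixes and realised geometrically (`mixed` eyes as
#' bombe-plus-thick quadrants). With the same seed the result is identical.
#'
#' @param spec a [cohort_spec()].
#' @return list with `roster` (data frame, one row per participant) and
#'   `recipes` (data frame, one row per included-participant quadrant, with
#'   the scan-recipe parameters).
#' @export
simulate_cohort <- function(spec = cohort_spec()) {
  with_seed(spec$seed, {
    st <- spec$strata
    band_ages <- list(`40-49` = 40:49, `50-59` = 50:59, `60-69` = 60:69, `70+` = 70:84)
    inc <- do.call(rbind, lapply(seq_len(nrow(st)), function(i) {
      n <- st$n[i]
      if (n == 0) return(NULL)
      data.frame(
        age = sample(band_ages[[st$age_band[i]]], n, replace = TRUE),
        gender = st$gender[i],
        hrac_label = stats::runif(n) < st$prevalence[i],
        stringsAsFactors = FALSE
      )
    }))
    n_inc <- nrow(inc)
    inc$pva_better_eye <- 1.0
    inc$iop_od <- 16; inc$iop_os <- 16
    inc$fundus_glaucoma_suspect <- FALSE
    inc$fundus_other_abnormal <- FALSE
    inc$prior_ocular_surgery <- FALSE
    inc$bilateral_poor_image <- FALSE
    pick <- function(prob, n) {
      sample(names(prob), n, replace = TRUE, prob = prob / sum(prob))
    }
    inc$configuration <- NA_character_
    if (any(inc$hrac_label)) {
      inc$configuration[inc$hrac_label] <- pick(spec$hrac_config_prob, sum(inc$hrac_label))
    }
    if (any(!inc$hrac_label)) {
      inc$configuration[!inc$hrac_label] <- pick(spec$non_hrac_config_prob, sum(!inc$hrac_label))
    }

    exc_reason <- rep(names(spec$exclusions), spec$exclusions)
    exc <- NULL
    if (length(exc_reason)) {
      n_exc <- length(exc_reason)
      exc <- data.frame(
        age = sample(40:84, n_exc, replace = TRUE),
        gender = sample(c("male", "female"), n_exc, replace = TRUE),
        hrac_label = NA,
        pva_better_eye = ifelse(exc_reason == "low_pva", 6 / 18, 1.0),
        iop_od = ifelse(exc_reason == "high_iop", 26, 16),
        iop_os = 16,
        fundus_glaucoma_suspect = exc_reason == "glaucoma_suspect",
        fundus_other_abnormal = exc_reason == "retinal_abnormal",
        prior_ocular_surgery = exc_reason == "prior_surgery",
        bilateral_poor_image = exc_reason == "poor_image",
        configuration = NA_character_,
        stringsAsFactors = FALSE
      )
    }
    roster <- rbind(inc, exc)
    roster <- cbind(id = sprintf("S%05d", seq_len(nrow(roster))), roster)
    rownames(roster) <- NULL

    # quadrant recipes for included participants (right eye)
    shape <- ifelse(inc$configuration == "mixed", "bombe_thick", inc$configuration)
    n_narrow <- integer(n_inc)
    hr <- inc$hrac_label
    n_narrow[hr] <- sample(3:4, sum(hr), replace = TRUE)
    n_narrow[!hr] <- sample(
      as.integer(names(spec$n_narrow_non_hrac_prob)), sum(!hr),
      replace = TRUE, prob = spec$n_narrow_non_hrac_prob
    )
    narrow_at <- matrix(FALSE, 4, n_inc)
    for (i in seq_len(n_inc)) {
      if (n_narrow[i] > 0) narrow_at[sample.int(4, n_narrow[i]), i] <- TRUE
    }
    tia <- stats::runif(4 * n_inc, spec$open_tia_range[1], spec$open_tia_range[2])
    sel <- which(as.vector(narrow_at))
    tia[sel] <- stats::runif(length(sel), spec$narrow_tia_range[1],
                             spec$narrow_tia_range[2])
    recipes <- data.frame(
      id = rep(roster$id[seq_len(n_inc)], each = 4),
      eye = "OD",
      quadrant = rep(quadrant_names, n_inc),
      configuration = rep(shape, each = 4),
      target_tia = tia,
      noise_seed = if (spec$noise_sd > 0) sample.int(2^30, 4 * n_inc) else NA_integer_,
      noise_sd = spec$noise_sd,
      n_vertices = spec$n_vertices,
      stringsAsFactors = FALSE
    )
    list(roster = roster, recipes = recipes)
  })
}

recipe_presets <- list(
  sagitta = c(flat = 0, bowing = -300, bombe = 400,
              thick_peripheral = 0, bombe_thick = 400),
  thickness = c(flat = 450, bowing = 450, bombe = 450,
                thick_peripheral = 700, bombe_thick = 700)
)

# Fast path from recipe parameters to an angle_scan (no re-validation;
# simulate_cohort only emits valid recipes).
scan_from_params <- function(configuration, target_tia, noise_sd, n_vertices,
                             noise_seed, quadrant) {
  generate_scan(list(
    configuration = configuration, target_tia = target_tia,
    cornea_wedge = 35, iris_chord = 3000,
    sagitta = recipe_presets$sagitta[[configuration]],
    thickness = recipe_presets$thickness[[configuration]],
    noise_sd = noise_sd, n_vertices = n_vertices,
    seed = if (!is.na(noise_seed)) noise_seed else NULL,
    quadrant = quadrant, spur_offset = 100
  ))
}
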