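exclusion_order <- c("poor_image", "low_pva", "high_iop",
                     "glaucoma_suspect", "retinal_abnormal", "prior_surgery")

roster_columns <- c(
  "id", "age", "gender", "pva_better_eye", "iop_od", "iop_os",
  "fundus_glaucoma_suspect", "fundus_other_abnormal",
  "prior_ocular_surgery", "bilateral_poor_image"
)

#' Convert Snellen fraction to logMAR (and back)
#'
#' Presenting visual acuity is stored as a Snellen fraction (6/12 = 0.5);
#' logMAR is its negative base-10 logarithm.
#'
#' @param snellen,logmar numeric vectors.
#' @return numeric vector.
#' @export
snellen_to_logmar <- function(snellen) -log10(snellen)

#' @rdname snellen_to_logmar
#' @export
logmar_to_snellen <- function(logmar) 10^(-logmar)

#' Validate a screening roster
#'
#' Checks required columns, ages >= 40, IOP inside (5, 80) mmHg and gender
#' labels; reports every failing record and field.
#'
#' @param roster data frame of participant records.
#' @return invisibly `roster`; stops with a record-level message on failure.
#' @export
validate_roster <- function(roster) {
  missing <- setdiff(roster_columns, names(roster))
  if (length(missing)) {
    ag_stop(paste0("roster is missing fields: ", paste(missing, collapse = ", ")),
            "invalid-roster")
  }
  problems <- character(0)
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i)) {
      problems <<- c(problems, sprintf("%s: records %s", what,
                                       paste(utils::head(roster$id[i], 5), collapse = ", ")))
    }
  }
  bad(is.na(roster$age) | roster$age < 40, "age below 40 or missing")
  bad(!(roster$gender %in% c("male", "female")), "gender not male/female")
  iop_bad <- function(x) is.na(x) | x <= 5 | x >= 80
  bad(iop_bad(roster$iop_od) | iop_bad(roster$iop_os), "IOP outside (5, 80) mmHg")
  bad(is.na(roster$pva_better_eye) | roster$pva_better_eye <= 0,
      "PVA fraction not positive")
  if (length(problems)) {
    ag_stop(paste0("invalid roster: ", paste(problems, collapse = "; ")),
            "invalid-roster")
  }
  invisible(roster)
}

#' Apply the screening exclusion cascade
#'
#' Assigns each participant to the first matching exclusion reason, in the
#' fixed precedence order bilateral poor image quality, PVA < 6/12 in the
#' better-seeing eye (Snellen fractions, strict), IOP >= 24 mmHg in the
#' worse eye, suspected glaucomatous neuropathy, other retinal abnormality,
#' prior ocular surgery; everyone else is included. Counts always conserve:
#' included + sum of exclusions = enrolled.
#'
#' @param roster validated data frame of participant records.
#' @return list with `included` (the surviving roster), `accounting` (an
#'   `exclusion_accounting` list with `n_enrolled`, per-reason `counts`,
#'   `n_included`) and `reasons` (per-record reason, `NA` for included).
#' @export
apply_exclusions <- function(roster) {
  validate_roster(roster)
  n <- nrow(roster)
  reason <- rep(NA_character_, n)
  hit <- function(cond, r) {
    sel <- is.na(reason) & cond & !is.na(cond)
    reason[sel] <<- r
  }
  hit(roster$bilateral_poor_image, "poor_image")
  hit(roster$pva_better_eye < 0.5, "low_pva")
  hit(pmax(roster$iop_od, roster$iop_os) >= 24, "high_iop")
  hit(roster$fundus_glaucoma_suspect, "glaucoma_suspect")
  hit(roster$fundus_other_abnormal, "retinal_abnormal")
  hit(roster$prior_ocular_surgery, "prior_surgery")
  counts <- vapply(exclusion_order, function(r) sum(reason == r, na.rm = TRUE),
                   integer(1))
  accounting <- structure(
    list(n_enrolled = n, counts = counts, n_included = n - sum(counts)),
    class = "exclusion_accounting"
  )
  list(included = roster[is.na(reason), , drop = FALSE],
       accounting = accounting, reasons = reason)
}

#' @export
print.exclusion_accounting <- function(x, ...) {
  cat(flowchart_text(x), sep = "\n")
  invisible(x)
}

#' Study-flow text for an exclusion accounting
#'
#' Renders the enrolment -> exclusion -> analysis flow as indented text
#' (the usual study flowchart, in plain characters).
#'
#' @param accounting an `exclusion_accounting` from [apply_exclusions()].
#' @return character vector of lines.
#' @export
flowchart_text <- function(accounting) {
  labels <- c(
    poor_image = "Bilateral poor image quality",
    low_pva = "PVA < 6/12 in the better-seeing eye",
    high_iop = "IOP >= 24 mmHg",
    glaucoma_suspect = "Suspected glaucomatous neuropathy",
    retinal_abnormal = "Other retinal abnormality",
    prior_surgery = "Previous ophthalmic surgery"
  )
  pct <- function(k) sprintf("%.1f%%", round_half_up(100 * k / accounting$n_enrolled, 1))
  c(
    sprintf("Enrolled: %d participants", accounting$n_enrolled),
    "Excluded:",
    sprintf("  %-38s %4d (%s)", labels[names(accounting$counts)],
            accounting$counts, vapply(accounting$counts, pct, character(1))),
    sprintf("Included in analysis: %d (%s)", accounting$n_included,
            pct(accounting$n_included))
  )
}

# Assess the four quadrants of one eye. `scans` is a list of angle_scan (any
# subset of the four quadrants; absent quadrants count as ungradable).
assess_eye <- function(scans, eye, config, thresholds, metrics = TRUE,
                       configurations = TRUE) {
  by_quadrant <- stats::setNames(vector("list", 4), quadrant_names)
  for (s in scans) by_quadrant[[s$quadrant]] <- s
  qas <- lapply(quadrant_names, function(q) {
    s <- by_quadrant[[q]]
    if (is.null(s)) {
      return(structure(
        list(quadrant = q, tia750 = NA_real_, aod750 = NA_real_,
             angle_class = "ungradable", iris_configuration = NA_character_,
             metrics_valid = FALSE, reason = "missing"),
        class = "quadrant_assessment"
      ))
    }
    qa <- classify_quadrant(s, config, metrics = metrics)
    if (configurations && qa$angle_class != "ungradable") {
      qa$iris_configuration <- tryCatch(
        classify_iris_configuration(s, thresholds),
        angleguard_error = function(e) NA_character_
      )
    }
    qa
  })
  ea <- aggregate_hrac(qas, eye = eye)
  ea$configuration <- tryCatch(
    eye_configuration(vapply(qas, function(q) q$iris_configuration, character(1))),
    angleguard_error = function(e) NA_character_
  )
  ea
}

#' Run the screening pipeline over an included roster
#'
#' For each included participant: select the analyzed eye (right unless two
#' or more of its quadrants are unidentifiable), classify its four quadrants
#' with the preset-angle rule, type the iris configuration, and aggregate to
#' the eye-level HRAC call. Participants without annotations, or with both
#' eyes failing the selection rule, are counted ungradable.
#'
#' @param roster included participant records (after [apply_exclusions()]).
#' @param annotations either a nested annotation list as returned by
#'   [read_annotations()], or a recipes data frame as produced by
#'   [simulate_cohort()] (scans are then generated on the fly).
#' @param config a [geometry_config()].
#' @param thresholds a [shape_thresholds()].
#' @param metrics compute TIA750/AOD750 per quadrant (disable for large
#'   simulations where only the class is needed).
#' @param configurations classify iris configurations per quadrant.
#' @return data frame with one row per participant: `id`, `eye`, `hrac`,
#'   `n_gradable`, `n_qualifying`, `appositional_closure`, `configuration`,
#'   per-quadrant angle classes and (when `metrics`) TIA/AOD values.
#' @export
run_screening <- function(roster, annotations, config = geometry_config(),
                          thresholds = shape_thresholds(), metrics = TRUE,
                          configurations = TRUE) {
  if (is.data.frame(annotations)) {
    # recipe rows: keep plain vectors and pre-split indices for speed
    rc <- as.list(annotations[c("id", "eye", "quadrant", "configuration",
                                "target_tia", "noise_sd", "n_vertices",
                                "noise_seed")])
    row_idx <- split(seq_len(nrow(annotations)),
                     paste(annotations$id, annotations$eye, sep = "\r"))
    get_eye_scans <- function(id, eye) {
      ii <- row_idx[[paste(id, eye, sep = "\r")]]
      if (is.null(ii)) return(NULL)
      lapply(ii, function(i) {
        scan_from_params(rc$configuration[i], rc$target_tia[i], rc$noise_sd[i],
                         rc$n_vertices[i], rc$noise_seed[i], rc$quadrant[i])
      })
    }
  } else {
    ann <- annotation_index(annotations)
    get_eye_scans <- function(id, eye) {
      e <- ann[[id]]
      if (is.null(e)) return(NULL)
      e[[eye]]
    }
  }

  n <- nrow(roster)
  out <- data.frame(
    id = roster$id, eye = NA_character_, hrac = NA,
    n_gradable = NA_integer_, n_qualifying = NA_integer_,
    appositional_closure = NA, configuration = NA_character_,
    stringsAsFactors = FALSE
  )
  qcls <- matrix(NA_character_, n, 4, dimnames = list(NULL, paste0("class_", quadrant_names)))
  qtia <- matrix(NA_real_, n, 4, dimnames = list(NULL, paste0("tia750_", quadrant_names)))
  qaod <- matrix(NA_real_, n, 4, dimnames = list(NULL, paste0("aod750_", quadrant_names)))

  for (i in seq_len(n)) {
    id <- roster$id[i]
    od_scans <- get_eye_scans(id, "OD")
    ea <- NULL
    od <- if (!is.null(od_scans)) {
      assess_eye(od_scans, "OD", config, thresholds, metrics, configurations)
    } else {
      4  # no right-eye annotation: all four quadrants unidentifiable
    }
    se <- select_eye(od, 4)
    if (!is.na(se) && se == "OD") {
      ea <- od
    } else {
      os_scans <- get_eye_scans(id, "OS")
      if (!is.null(os_scans)) {
        os <- assess_eye(os_scans, "OS", config, thresholds, metrics, configurations)
        se2 <- select_eye(od, os)
        if (!is.na(se2) && se2 == "OS") ea <- os
      }
    }
    if (is.null(ea)) next  # participant ungradable (no usable eye)
    out$eye[i] <- ea$eye
    out$hrac[i] <- ea$hrac
    out$n_gradable[i] <- ea$n_gradable
    out$n_qualifying[i] <- ea$n_qualifying
    out$appositional_closure[i] <- ea$appositional_closure
    out$configuration[i] <- ea$configuration
    qcls[i, ] <- ea$classes
    if (metrics) {
      qtia[i, ] <- vapply(ea$quadrants, function(q) q$tia750, numeric(1))
      qaod[i, ] <- vapply(ea$quadrants, function(q) q$aod750, numeric(1))
    }
  }
  out <- cbind(out, as.data.frame(qcls, stringsAsFactors = FALSE))
  if (metrics) out <- cbind(out, as.data.frame(qtia), as.data.frame(qaod))
  out
}

#' Stratified screening summary
#'
#' Joins grading results back to the roster and tabulates HRAC by gender and
#' decade age band, plus the iris-configuration distribution by HRAC status.
#'
#' @param results data frame from [run_screening()].
#' @param roster the roster the results were computed from.
#' @return list with `stratified` (gender x age-band numerators and
#'   denominators over participants with a definite HRAC call),
#'   `configurations` (counts by HRAC status) and `n_ungradable`.
#' @export
screening_summary <- function(results, roster) {
  m <- merge(results, roster[c("id", "age", "gender")], by = "id")
  m$age_band <- age_band(m$age)
  graded <- m[!is.na(m$hrac), , drop = FALSE]
  grid <- expand.grid(gender = c("male", "female"), age_band = age_bands,
                      stringsAsFactors = FALSE)
  grid$denominator <- mapply(function(g, b) {
    sum(graded$gender == g & graded$age_band == b)
  }, grid$gender, grid$age_band)
  grid$numerator <- mapply(function(g, b) {
    sum(graded$hrac & graded$gender == g & graded$age_band == b)
  }, grid$gender, grid$age_band)
  cfg <- table(
    factor(graded$configuration, levels = iris_configurations),
    factor(ifelse(graded$hrac, "hrac", "non_hrac"), levels = c("hrac", "non_hrac"))
  )
  list(
    stratified = grid[c("gender", "age_band", "numerator", "denominator")],
    configurations = as.data.frame.matrix(cfg),
    n_ungradable = sum(is.na(m$hrac))
  )
}

#' Read / write a screening roster CSV
#'
#' Plain CSV with the participant-record columns; logical flags are stored
#' as TRUE/FALSE.
#'
#' @param path file path.
#' @param roster data frame of participant records.
#' @return `read_roster()` returns the validated data frame.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("fundus_glaucoma_suspect", "fundus_other_abnormal",
                "prior_ocular_surgery", "bilateral_poor_image")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  validate_roster(df)
  df
}

#' @rdname read_roster
#' @export
write_roster <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE)
  invisible(path)
}
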