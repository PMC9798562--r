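annotation_schema <- "angleguard-annotation-v1"

#' Write boundary-trace annotations to JSON
#'
#' Serialises per-eye angle scans into the package's annotation format: one
#' object per eye holding `participant_id`, `eye` ("OD"/"OS") and the four
#' quadrant scans (traces as `[[x, y], ...]` arrays in micrometres, plus the
#' scleral-spur and iris-recess landmarks and the gradable flag), under a
#' `schema` version field.
#'
#' @param eyes list of eye records: each a list with `participant_id`, `eye`,
#'   and `scans` (a list of [angle_scan()]).
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_annotations <- function(eyes, path) {
  ser_scan <- function(s) {
    list(
      quadrant = s$quadrant,
      pixel_scale_um = 1,  # coordinates are stored in um
      cornea_inner = unname(s$cornea_inner),
      iris_anterior = unname(s$iris_anterior),
      iris_posterior = if (!is.null(s$iris_posterior)) unname(s$iris_posterior),
      scleral_spur = s$scleral_spur,
      iris_recess = s$iris_recess,
      gradable = s$gradable
    )
  }
  doc <- list(
    schema = annotation_schema,
    eyes = lapply(eyes, function(e) {
      list(participant_id = e$participant_id, eye = e$eye,
           scans = lapply(e$scans, ser_scan))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read boundary-trace annotations from JSON
#'
#' Parses and validates an annotation file written in the
#' `angleguard-annotation-v1` schema. Every scan is checked against the
#' [angle_scan()] invariants; scans with violations are kept but downgraded
#' to ungradable, and all per-field failures are collected in
#' `attr(x, "problems")`. The local frame is normalised so the cornea lies on
#' the positive-y side of the iris.
#'
#' @param path annotation JSON file.
#' @return list of eye records (`participant_id`, `eye`, `scans`), with a
#'   `problems` attribute (character vector, empty when clean).
#' @export
read_annotations <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  if (!identical(doc$schema, annotation_schema)) {
    ag_stop(sprintf("unsupported annotation schema: %s", doc$schema %||% "<missing>"),
            "bad-schema")
  }
  problems <- character(0)
  eyes <- lapply(doc$eyes, function(e) {
    scans <- lapply(e$scans, function(sc) {
      tag <- sprintf("%s/%s/%s", e$participant_id, e$eye, sc$quadrant)
      s <- tryCatch(
        angle_scan(
          quadrant = sc$quadrant,
          cornea_inner = sc$cornea_inner,
          iris_anterior = sc$iris_anterior,
          iris_posterior = sc$iris_posterior,
          scleral_spur = unlist(sc$scleral_spur),
          iris_recess = unlist(sc$iris_recess),
          pixel_scale = sc$pixel_scale_um %||% 1,
          gradable = isTRUE(sc$gradable),
          validate = FALSE
        ),
        error = function(err) {
          problems <<- c(problems, sprintf("%s: %s", tag, conditionMessage(err)))
          NULL
        }
      )
      if (is.null(s)) return(NULL)
      pr <- validate_angle_scan(s)
      if (length(pr)) {
        problems <<- c(problems, sprintf("%s: %s", tag, pr))
        s$gradable <- FALSE
      }
      normalize_scan_orientation(s)
    })
    list(participant_id = e$participant_id, eye = e$eye,
         scans = Filter(Negate(is.null), scans))
  })
  attr(eyes, "problems") <- problems
  eyes
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reflect the local frame about the x axis when the cornea sits below the
# iris, so the cornea is always on the positive-y side.
normalize_scan_orientation <- function(scan) {
  if (mean(scan$cornea_inner[, 2]) >= mean(scan$iris_anterior[, 2])) return(scan)
  flip <- function(m) { m[, 2] <- -m[, 2]; m }
  scan$cornea_inner <- flip(scan$cornea_inner)
  scan$iris_anterior <- flip(scan$iris_anterior)
  if (!is.null(scan$iris_posterior)) scan$iris_posterior <- flip(scan$iris_posterior)
  scan$scleral_spur[2] <- -scan$scleral_spur[2]
  scan$iris_recess[2] <- -scan$iris_recess[2]
  scan
}

# id -> eye -> list of scans, for the screening driver.
annotation_index <- function(eyes) {
  idx <- list()
  for (e in eyes) {
    id <- as.character(e$participant_id)
    if (is.null(idx[[id]])) idx[[id]] <- list()
    idx[[id]][[e$eye]] <- e$scans
  }
  idx
}
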