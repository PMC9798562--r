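#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the grading pipeline) can distinguish
# geometric failure modes; `reason` becomes a condition class.
ag_stop <- function(message, reason) {
  stop(structure(
    class = c(reason, "angleguard_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

is_point <- function(p) is.numeric(p) && length(p) == 2 && all(is.finite(p))

#' Round half away from zero
#'
#' Decimal rounding with ties going up (half-up), the convention used when
#' rendering percentages; base [round()] rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a p-value for reporting
#'
#' Three decimals with a "< 0.001" floor.
#'
#' @param p p-value in `[0, 1]`.
#' @return character scalar.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "< 0.001", sprintf("%.3f", p))
}

# Evaluate `expr` with a private RNG stream seeded by `seed` (if non-NULL),
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
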