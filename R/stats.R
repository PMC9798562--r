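#' Stratified prevalence table
#'
#' Expands gender-by-age-band numerator/denominator cells into a tidy table
#' with row (age), column (gender) and grand-total margins. Percentages are
#' `100 * numerator / denominator` rounded half-up to one decimal; cells with
#' zero denominator render as `NA` (printed "-").
#'
#' @param cells data frame with columns `gender`, `age_band`, `numerator`,
#'   `denominator`.
#' @param margins optional list with `age_totals`, `gender_totals`, `overall`
#'   (as in [reference_counts()]) to use as printed marginals instead of the
#'   cell sums; by default margins are the sums of the cells.
#' @return data frame with columns `gender` (including `"total"`), `age_band`
#'   (including `"total"`), `numerator`, `denominator`, `pct`, `label`.
#' @export
prevalence_table <- function(cells, margins = NULL) {
  stopifnot(all(c("gender", "age_band", "numerator", "denominator") %in% names(cells)))
  if (any(cells$numerator < 0 | cells$denominator < 0 |
            cells$numerator > cells$denominator)) {
    ag_stop("cells need 0 <= numerator <= denominator", "bad-counts")
  }
  agg <- function(by) {
    n <- tapply(cells$numerator, cells[[by]], sum)
    d <- tapply(cells$denominator, cells[[by]], sum)
    data.frame(level = names(n), numerator = as.vector(n), denominator = as.vector(d),
               stringsAsFactors = FALSE)
  }
  if (is.null(margins)) {
    at <- agg("age_band"); names(at)[1] <- "age_band"
    gt <- agg("gender"); names(gt)[1] <- "gender"
    ov <- c(numerator = sum(cells$numerator), denominator = sum(cells$denominator))
  } else {
    at <- margins$age_totals; gt <- margins$gender_totals; ov <- margins$overall
  }
  rows <- rbind(
    cells[c("gender", "age_band", "numerator", "denominator")],
    data.frame(gender = "total", age_band = at$age_band,
               numerator = at$numerator, denominator = at$denominator),
    data.frame(gender = gt$gender, age_band = "total",
               numerator = gt$numerator, denominator = gt$denominator),
    data.frame(gender = "total", age_band = "total",
               numerator = ov[["numerator"]], denominator = ov[["denominator"]])
  )
  rows$pct <- ifelse(rows$denominator > 0,
                     round_half_up(100 * rows$numerator / rows$denominator, 1),
                     NA_real_)
  rows$label <- ifelse(
    is.na(rows$pct), "-",
    sprintf("%d/%d (%.1f%%)", rows$numerator, rows$denominator, rows$pct)
  )
  rownames(rows) <- NULL
  rows
}

#' Pearson chi-square test on a 2 x k contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction), as used
#' for the categorical comparisons in the screening analysis; the uncorrected
#' statistic is what reproduces the published gender and age-band p-values.
#'
#' @param table 2 x k (or k x 2) matrix of non-negative counts.
#' @return list with `method`, `statistic`, `df`, `p_value`, `p_label`.
#' @export
pearson_chisq <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m))) {
    ag_stop("counts must be non-negative integers", "bad-counts")
  }
  if (min(dim(m)) < 2) ag_stop("table must be at least 2 x 2", "bad-counts")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    ag_stop("table has a zero margin", "degenerate-table")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(
    method = "pearson-chisq",
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value),
    p_label = format_p(unname(ct$p.value))
  )
}

#' Compare a continuous measure between two groups
#'
#' Student's t test when both samples pass Shapiro-Wilk normality at
#' `alpha` (the policy used for the cohort's continuous comparisons),
#' otherwise the Mann-Whitney U test; the choice can be forced via `policy`.
#'
#' @param x,y numeric samples (each n >= 3).
#' @param policy `"auto"` (normality-gated), `"t"` or `"wilcoxon"`.
#' @param alpha significance level of the normality gate (default 0.05).
#' @return list with `method` (`"student-t"` or `"mann-whitney"`),
#'   `statistic`, `p_value`, `p_label` and the two Shapiro-Wilk p-values
#'   (`NA` unless `policy = "auto"`).
#' @export
compare_continuous <- function(x, y, policy = c("auto", "t", "wilcoxon"),
                               alpha = 0.05) {
  policy <- match.arg(policy)
  if (length(x) < 3 || length(y) < 3) {
    ag_stop("both samples need at least 3 observations", "insufficient-sample")
  }
  shapiro_p <- c(x = NA_real_, y = NA_real_)
  use_t <- policy == "t"
  if (policy == "auto") {
    sw <- function(v) {
      if (length(v) > 5000) v <- v[seq(1, length(v), length.out = 5000)]
      tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
    }
    shapiro_p <- c(x = sw(x), y = sw(y))
    use_t <- all(shapiro_p > alpha)
  }
  if (use_t) {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    res <- list(method = "student-t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    res <- list(method = "mann-whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  res$p_label <- format_p(res$p_value)
  res$shapiro_p <- shapiro_p
  res
}

#' Render the stratified HRAC prevalence grid (age x gender with tests)
#'
#' Builds the age-by-gender prevalence grid with per-row (between-gender) and
#' per-column (between-age) uncorrected Pearson chi-square p-values, as both
#' a data frame and Markdown lines.
#'
#' @param cells gender x age-band cells (as in [reference_counts()]`$cells`
#'   or [screening_summary()]`$stratified`).
#' @param margins optional printed marginals (see [prevalence_table()]).
#' @return list with `table` (data frame: one row per age band plus total,
#'   columns men/women/total labels and `p_value`) and `markdown` lines.
#' @export
render_table2 <- function(cells, margins = NULL) {
  pt <- prevalence_table(cells, margins)
  get <- function(g, b) pt[pt$gender == g & pt$age_band == b, ]
  bands <- unique(cells$age_band)
  row_p <- function(b) {
    m <- get("male", b); w <- get("female", b)
    tab <- rbind(c(m$numerator, m$denominator - m$numerator),
                 c(w$numerator, w$denominator - w$numerator))
    tryCatch(pearson_chisq(tab)$p_value, angleguard_error = function(e) NA_real_)
  }
  col_p <- function(g) {
    sub <- pt[pt$gender == g & pt$age_band != "total", ]
    tab <- rbind(sub$numerator, sub$denominator - sub$numerator)
    tryCatch(pearson_chisq(tab)$p_value, angleguard_error = function(e) NA_real_)
  }
  tab <- data.frame(
    age_band = c(bands, "total"),
    men = vapply(c(bands, "total"), function(b) get("male", b)$label, character(1)),
    women = vapply(c(bands, "total"), function(b) get("female", b)$label, character(1)),
    total = vapply(c(bands, "total"), function(b) get("total", b)$label, character(1)),
    p_value = c(vapply(bands, row_p, numeric(1)), row_p("total")),
    stringsAsFactors = FALSE
  )
  tab$p_label <- ifelse(is.na(tab$p_value), "-", format_p(tab$p_value))
  md <- c(
    "| Age, years | Men | Women | Total | P value |",
    "|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %s | %s |",
            tab$age_band, tab$men, tab$women, tab$total, tab$p_label),
    sprintf("| P value | %s | %s | %s | |",
            format_p(col_p("male")), format_p(col_p("female")), format_p(col_p("total")))
  )
  list(table = tab, markdown = md,
       column_p = c(male = col_p("male"), female = col_p("female"),
                    total = col_p("total")))
}

#' Render the cohort-characteristics table (HRAC vs non-HRAC)
#'
#' Formats group characteristics and the iris-configuration distribution of
#' participants with and without HRAC, with tests: continuous rows via
#' [compare_continuous()], the configuration block via a single
#' [pearson_chisq()] over the 5 x 2 count table.
#'
#' @param hrac,non_hrac lists of numeric vectors of per-participant values
#'   (e.g. `age`, `pva_logmar`, `iop`), same names in both.
#' @param configurations data frame with `configuration`, `hrac`, `non_hrac`
#'   counts (as in [reference_counts()]`$configurations`).
#' @return list with `characteristics` and `configuration` data frames and
#'   `markdown` lines.
#' @export
render_table1 <- function(hrac, non_hrac, configurations) {
  stopifnot(identical(names(hrac), names(non_hrac)))
  chars <- do.call(rbind, lapply(names(hrac), function(v) {
    ts <- tryCatch(compare_continuous(hrac[[v]], non_hrac[[v]]),
                   angleguard_error = function(e) list(p_value = NA_real_))
    data.frame(
      characteristic = v,
      hrac = sprintf("%.1f ± %.1f", mean(hrac[[v]]), stats::sd(hrac[[v]])),
      non_hrac = sprintf("%.1f ± %.1f", mean(non_hrac[[v]]), stats::sd(non_hrac[[v]])),
      p_value = ts$p_value,
      stringsAsFactors = FALSE
    )
  }))
  cfg <- configurations
  pcts <- function(k) {
    tot <- sum(k)
    if (tot == 0) rep("0 (0.0)", length(k))
    else sprintf("%d (%.1f)", k, round_half_up(100 * k / tot, 1))
  }
  cfg_out <- data.frame(
    configuration = cfg$configuration,
    hrac = pcts(cfg$hrac), non_hrac = pcts(cfg$non_hrac),
    stringsAsFactors = FALSE
  )
  cfg_p <- tryCatch(
    pearson_chisq(cbind(cfg$hrac, cfg$non_hrac))$p_value,
    angleguard_error = function(e) NA_real_
  )
  md <- c(
    sprintf("| Characteristic | With HRAC (N = %d) | Without HRAC (N = %d) | P value |",
            sum(cfg$hrac), sum(cfg$non_hrac)),
    "|---|---|---|---|",
    sprintf("| %s | %s | %s | %s |", chars$characteristic, chars$hrac,
            chars$non_hrac, ifelse(is.na(chars$p_value), "-", format_p(chars$p_value))),
    sprintf("| Iris configuration (n, %%) | | | %s |",
            ifelse(is.na(cfg_p), "-", format_p(cfg_p))),
    sprintf("| %s | %s | %s | |", cfg_out$configuration, cfg_out$hrac, cfg_out$non_hrac)
  )
  list(characteristics = chars, configuration = cfg_out,
       configuration_p = cfg_p, markdown = md)
}
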