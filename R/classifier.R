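#' Classify one trait into the invariance verdict grid
#'
#' Aggregates the type I battery (variance ratio, unimodality, coverage) and
#' the type II battery (OLS slope, PGLS slope, R-squared) into per-criterion
#' marks -- `pass`, `marginal`, `fail`, or `not_available` -- and the three
#' boolean verdicts: type I, type II, and type I+II (their conjunction).
#' Marginal coverage (between 94% and 95%) yields the `"(+)"` mark and
#' counts toward type I only when the type-1 result was computed with
#' `lenient = TRUE`.  A missing PGLS leaves type II `NA` unless the
#' type-2 verdict was computed in degraded (OLS-only) mode.
#'
#' @param t1 a [type1_test()] result, or `NULL`.
#' @param t2 an [evaluate_type2()] result, or `NULL`.
#' @param trait trait name for the report row (defaults to `t1$trait`).
#' @return a one-row classification record (class `invariance_row`).
#' @export
classify_trait <- function(t1, t2, trait = NULL) {
  mark <- function(x, marginal = FALSE) {
    if (is.null(x) || is.na(x)) "not_available"
    else if (isTRUE(marginal)) "marginal"
    else if (isTRUE(x)) "pass" else "fail"
  }
  if (is.null(trait)) trait <- if (!is.null(t1)) t1$trait else "?"
  m_c1 <- mark(if (is.null(t1) || t1$insufficient) NA else t1$variance_ratio$pass_c1)
  m_uni <- mark(if (is.null(t1) || t1$insufficient) NA else t1$pass_unimodal)
  m_cov <- if (is.null(t1) || t1$insufficient) "not_available"
    else if (t1$pass_coverage) "pass"
    else if (t1$marginal_coverage) "marginal" else "fail"
  m_ols <- mark(if (is.null(t2)) NA else t2$pass_ols_slope)
  m_pgls <- mark(if (is.null(t2)) NA else t2$pass_pgls_slope)
  m_r2 <- mark(if (is.null(t2)) NA else t2$pass_r2)
  type_I <- if (is.null(t1) || t1$insufficient) NA else t1$verdict_type1
  type_II <- if (is.null(t2)) NA else t2$verdict_type2
  type_I_II <- if (is.na(type_I) || is.na(type_II)) NA else (type_I && type_II)
  structure(list(trait = trait,
                 marks = c(criterion1 = m_c1, unimodality = m_uni,
                           coverage = m_cov, ols_slope = m_ols,
                           pgls_slope = m_pgls, r2 = m_r2),
                 type_I = type_I, type_II = type_II, type_I_II = type_I_II,
                 t1 = t1, t2 = t2),
            class = "invariance_row")
}

#' Assemble an invariance report for one analysis group
#'
#' Collects classification rows into the verdict grid, one row per trait in
#' the supplied (configuration) order, rendered with the conventional marks:
#' `+` criterion fulfilled, `(+)` marginally fulfilled, `-` not fulfilled,
#' and an en dash for unavailable cells.
#'
#' @param rows list of [classify_trait()] rows.
#' @param group group label.
#' @return object of class `invariance_report`.
#' @export
build_report <- function(rows, group) {
  stopifnot(length(rows) >= 1)
  names(rows) <- vapply(rows, function(r) r$trait, "")
  structure(list(group = group, rows = rows), class = "invariance_report")
}

mark_symbol <- function(m) {
  switch(m, pass = "+", marginal = "(+)", fail = "-", not_available = "–")
}

verdict_symbol <- function(v) {
  if (is.na(v)) "–" else if (v) "yes" else "no"
}

#' Render an invariance report as a character matrix
#'
#' @param report an [build_report()] result.
#' @return character matrix: criteria and verdicts by trait.
#' @export
report_grid <- function(report) {
  crit <- c("criterion1", "unimodality", "coverage", "ols_slope",
            "pgls_slope", "r2")
  m <- vapply(report$rows, function(r) {
    c(vapply(r$marks[crit], mark_symbol, ""),
      type_I = verdict_symbol(r$type_I),
      type_II = verdict_symbol(r$type_II),
      type_I_II = verdict_symbol(r$type_I_II))
  }, character(length(crit) + 3))
  rownames(m) <- c("Criterion 1 (variance ratio)", "Unimodality (dip)",
                   "95% within ±2 SD", "Slope OLS", "Slope PGLS",
                   "R²", "Type I", "Type II", "Type I+II")
  m
}

#' @export
print.invariance_report <- function(x, ...) {
  cat("Invariance report --", x$group, "\n")
  print(report_grid(x), quote = FALSE)
  invisible(x)
}
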