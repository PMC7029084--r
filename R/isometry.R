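#' Standardized major axis regression (criterion 5)
#'
#' SMA fits a line to a trait-versus-trait scatter treating both axes
#' symmetrically: the slope is `sign(r) * SD_y / SD_x` and swapping the axes
#' maps the slope to its reciprocal.  An isometric relationship (slope of 1
#' on the log10-log10 scale) between two traits means their ratio does not
#' change along the joint range -- the classical dimensionless-number
#' signature of a trade-off.
#'
#' The 95% confidence interval of the slope uses the F-based factor
#' `slope * (sqrt(B + 1) +/- sqrt(B))` with
#' `B = F(0.95; 1, n-2) (1 - r^2)/(n - 2)`; the correlation test supplies
#' the p-value, since the SMA slope is significant exactly when the
#' correlation is.
#'
#' @param x,y numeric vectors (log10 trait values).
#' @param conf confidence level (default 0.95).
#' @return object of class `sma_fit` with slope, intercept, intervals,
#'   `r2`, `p_corr`, `n`.
#' @export
sma_fit <- function(x, y, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("sma_fit needs at least 3 complete pairs (got ", n, ")")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("sma_fit: constant variable")
  r <- stats::cor(x, y)
  if (r == 0) stop("sma_fit: zero correlation, slope sign undefined")
  slope <- sign(r) * sy / sx
  intercept <- mean(y) - slope * mean(x)
  B <- stats::qf(conf, 1, n - 2) * (1 - r^2) / (n - 2)
  ci <- sort(slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  p_corr <- stats::cor.test(x, y)$p.value
  # elevation interval: var(a) = s2_res/n + xbar^2 var(b)
  s2_res <- sy^2 - 2 * slope * stats::cov(x, y) + slope^2 * sx^2
  var_b <- slope^2 * (1 - r^2) / (n - 2)
  se_a <- sqrt(s2_res / n + mean(x)^2 * var_b)
  tq <- stats::qt(1 - (1 - conf) / 2, n - 2)
  structure(list(slope = slope, intercept = intercept,
                 slope_ci = ci, intercept_ci = intercept + c(-1, 1) * tq * se_a,
                 r2 = r^2, p_corr = p_corr, n = n),
            class = "sma_fit")
}

#' Isometry verdict for an SMA fit
#'
#' A pair is flagged isometric when the SMA slope differs significantly from
#' zero (correlation test) *and* unity lies within the slope's 95%
#' confidence interval.
#'
#' @param fit an [sma_fit()].
#' @param alpha significance level.
#' @return list with `significant` and `isometric`.
#' @export
isometry_verdict <- function(fit, alpha = 0.05) {
  significant <- fit$p_corr < alpha
  isometric <- significant && fit$slope_ci[1] <= 1 && 1 <= fit$slope_ci[2]
  list(significant = significant, isometric = isometric)
}

#' SMA scan over all trait pairs
#'
#' Fits SMA regressions on log10-transformed data for every unordered pair
#' of the requested traits with at least `min_n` complete cases, and attaches
#' the isometry verdict.  Pairs with too few cases are listed as skipped.
#' The earlier trait in `traits` order is used as the x variable, making the
#' report deterministic (SMA itself is symmetric up to slope inversion).
#' No phylogenetic correction is applied to SMA; a phylogeny-informed
#' reduced major axis regression would be the natural extension but is not
#' implemented here.
#'
#' @param table a [trait_table()] subset to the analysis group.
#' @param traits character vector of trait names (>= 2).
#' @param alpha significance level for the correlation test.
#' @param min_n minimum number of complete cases per pair (default 5).
#' @return object of class `sma_scan`: list with `fits` (one element per
#'   fitted pair: `pair`, `fit`, `verdict`, `n`) and `skipped`.
#' @export
scan_pairs <- function(table, traits, alpha = 0.05, min_n = 5) {
  traits <- intersect(traits, attr(table, "traits"))
  stopifnot(length(traits) >= 2)
  fits <- list(); skipped <- list()
  for (i in seq_len(length(traits) - 1)) for (j in (i + 1):length(traits)) {
    tx <- traits[i]; ty <- traits[j]
    ok <- !is.na(table[[tx]]) & !is.na(table[[ty]])
    n <- sum(ok)
    pair_id <- paste(ty, "~", tx)
    if (n < min_n) {
      skipped[[pair_id]] <- list(pair = c(tx, ty), n = n,
                                 reason = sprintf("only %d complete cases (min %d)", n, min_n))
      next
    }
    fit <- tryCatch(sma_fit(log10(table[[tx]][ok]), log10(table[[ty]][ok])),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      skipped[[pair_id]] <- list(pair = c(tx, ty), n = n,
                                 reason = conditionMessage(fit))
      next
    }
    fits[[pair_id]] <- list(pair = c(tx, ty), fit = fit,
                            verdict = isometry_verdict(fit, alpha), n = n)
  }
  structure(list(fits = fits, skipped = skipped, alpha = alpha, min_n = min_n),
            class = "sma_scan")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA: slope %.3f (%.3f, %.3f), intercept %.3f, R2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept, x$r2,
              x$p_corr, x$n))
  invisible(x)
}
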