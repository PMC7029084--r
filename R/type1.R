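#' Median-normalized variance ratio (criterion 1)
#'
#' Tests whether a trait varies much less than body mass does.  Raw trait
#' values and body masses are first divided by their within-group medians --
#' which makes variances comparable across traits measured in different
#' units and across groups with very different mass ranges -- then
#' log10-transformed, and the ratio Var(log10 mass) / Var(log10 trait) is
#' formed.  A ratio above unity passes the criterion.
#'
#' The body-mass variance is computed over *all* species in the group with a
#' recorded mass, not only those that also carry the trait, so a group has a
#' single implied mass variance shared by all of its traits.
#'
#' Because dividing by a constant only shifts logarithms, the normalization
#' cannot change the variance: Var(log10(x/median)) equals Var(log10 x)
#' exactly.  The implementation asserts this identity at machine precision
#' and keeps the median step for reporting fidelity.
#'
#' @param table a [trait_table()] already subset to the analysis group.
#' @param trait trait name.
#' @return object of class `variance_ratio`: trait/mass variances (log10,
#'   dimensionless), their ratio, sample sizes, and `pass_c1`.
#' @export
normalized_variance_ratio <- function(table, trait) {
  if (!trait %in% attr(table, "traits")) stop("unknown trait: ", trait)
  mass <- table$body_mass[!is.na(table$body_mass)]
  tv <- table[[trait]][!is.na(table[[trait]])]
  if (length(mass) < 2 || length(tv) < 2)
    return(structure(list(trait = trait, trait_var = NA_real_,
                          mass_var = NA_real_, ratio = NA_real_,
                          n_mass = length(mass), n_trait = length(tv),
                          pass_c1 = NA, insufficient = TRUE),
                     class = "variance_ratio"))
  lt <- log10(tv / stats::median(tv))
  lm_ <- log10(mass / stats::median(mass))
  trait_var <- stats::var(lt)
  mass_var <- stats::var(lm_)
  # normalization theorem: the median division is a constant shift of logs
  stopifnot(abs(trait_var - stats::var(log10(tv))) <=
              1e-10 * max(1, trait_var),
            abs(mass_var - stats::var(log10(mass))) <=
              1e-10 * max(1, mass_var))
  ratio <- mass_var / trait_var
  structure(list(trait = trait, trait_var = trait_var, mass_var = mass_var,
                 ratio = ratio, n_mass = length(mass), n_trait = length(tv),
                 pass_c1 = ratio > 1, insufficient = FALSE),
            class = "variance_ratio")
}

#' Coverage of the mean +/- 2 SD interval
#'
#' Percentage of sample values lying within two (n-1 denominator) standard
#' deviations of the mean; boundary values count as inside.  Under
#' normality about 95.45% of values are expected inside; Chebyshev bounds
#' the coverage below by 75%.
#'
#' @param x numeric sample (log10 trait values), length >= 2.
#' @return list with `mean`, `sd`, `coverage` (percent).
#' @export
coverage_two_sd <- function(x) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 2)
  m <- mean(x); s <- stats::sd(x)
  if (s == 0) {
    warning("zero standard deviation; coverage set to 100%", call. = FALSE)
    return(list(mean = m, sd = s, coverage = 100))
  }
  list(mean = m, sd = s, coverage = 100 * mean(abs(x - m) <= 2 * s))
}

#' Type I invariance tests for one trait in one group
#'
#' Combines criterion 1 (median-normalized variance ratio above unity) with
#' criterion 2 (unimodality by Hartigan's dip test, plus at least 95% of
#' log10 values within +/-2 SD of the mean).  Coverage strictly above 94%
#' but below 95% is recorded as "marginal"; it counts towards the type I
#' verdict only when `lenient = TRUE`.
#'
#' @param table a [trait_table()] already subset to the group.
#' @param trait trait name.
#' @param alpha significance level for the dip test (default 0.05).
#' @param n_mc Monte-Carlo replicates for the dip p-value.
#' @param seed seed for the dip Monte Carlo.
#' @param lenient whether marginal coverage counts as passing.
#' @param coverage_pass,coverage_marginal thresholds (percent).
#' @param dip_min_n minimum sample size for the dip test.
#' @return object of class `type1_result`.
#' @export
type1_test <- function(table, trait, alpha = 0.05, n_mc = 10000, seed = NULL,
                       lenient = FALSE, coverage_pass = 95,
                       coverage_marginal = 94, dip_min_n = 4) {
  vr <- normalized_variance_ratio(table, trait)
  tv <- table[[trait]][!is.na(table[[trait]])]
  if (length(tv) < 2) {
    out <- list(trait = trait, variance_ratio = vr, dip = NULL, mean = NA_real_,
                sd = NA_real_, coverage = NA_real_, pass_unimodal = NA,
                pass_coverage = NA, marginal_coverage = NA,
                verdict_type1 = NA, insufficient = TRUE)
    class(out) <- "type1_result"
    return(out)
  }
  lx <- log10(tv)
  dip <- dip_pvalue(lx, n_mc = n_mc, seed = seed, min_n = dip_min_n)
  cov2 <- coverage_two_sd(lx)
  pass_unimodal <- if (dip$insufficient) NA else dip$p >= alpha
  pass_coverage <- cov2$coverage >= coverage_pass
  marginal <- cov2$coverage > coverage_marginal && cov2$coverage < coverage_pass
  cov_ok <- pass_coverage || (lenient && marginal)
  verdict <- isTRUE(vr$pass_c1) && isTRUE(pass_unimodal) && cov_ok
  if (is.na(pass_unimodal) || vr$insufficient) verdict <- NA
  structure(list(trait = trait, variance_ratio = vr, dip = dip,
                 mean = cov2$mean, sd = cov2$sd, coverage = cov2$coverage,
                 pass_unimodal = pass_unimodal, pass_coverage = pass_coverage,
                 marginal_coverage = marginal, verdict_type1 = verdict,
                 lenient = lenient, insufficient = FALSE),
            class = "type1_result")
}

#' @export
print.type1_result <- function(x, ...) {
  cat("Type I invariance --", x$trait, "\n")
  if (isTRUE(x$insufficient)) { cat("  insufficient sample\n"); return(invisible(x)) }
  cat(sprintf("  mass var / trait var = %.2f (%s)\n", x$variance_ratio$ratio,
              if (isTRUE(x$variance_ratio$pass_c1)) "pass" else "fail"))
  if (!is.null(x$dip) && !x$dip$insufficient)
    cat(sprintf("  dip D = %.3f, p = %.3f\n", x$dip$D, x$dip$p))
  cat(sprintf("  %% within +/-2 SD = %.2f\n", x$coverage))
  cat("  verdict:", if (isTRUE(x$verdict_type1)) "type I invariant"
      else if (is.na(x$verdict_type1)) "not available" else "not invariant", "\n")
  invisible(x)
}
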