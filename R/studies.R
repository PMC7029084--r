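#' End-to-end classification recovery study
#'
#' Repeatedly simulates a comparative dataset containing one genuinely
#' invariant trait (i.i.d. lognormal, `sigma = 0.05` on the log10 scale) and
#' one genuinely allometric trait (`b = 0.4`, residual `sigma = 0.1`,
#' phylogenetic signal `lambda = 0.8`), runs the full five-criterion
#' classifier, and records how often each trait is classified correctly:
#' the invariant trait as type I+II invariant, the allometric trait as not.
#'
#' @param n_seeds number of replicate datasets (seeds `1..n_seeds` offset by
#'   `seed_offset`).
#' @param n_species tips per dataset.
#' @param n_mc dip-test Monte-Carlo replicates per trait.
#' @param lenient whether marginal coverage counts toward type I.
#' @param seed_offset added to each replicate seed.
#' @param b,sigma_allo,lambda,sigma_inv generating parameters.
#' @return list of rates: `invariant_correct_rate`, `allometric_rejected_rate`,
#'   `joint_correct_rate`, plus per-replicate logicals.
#' @export
recovery_study <- function(n_seeds = 100, n_species = 200, n_mc = 1000,
                           lenient = FALSE, seed_offset = 0, b = 0.4,
                           sigma_allo = 0.1, lambda = 0.8, sigma_inv = 0.05) {
  inv_ok <- allo_ok <- logical(n_seeds)
  specs <- list(
    list(name = "inv", kind = "invariant", a = 30, b = 0, sigma = sigma_inv,
         lambda = 0, missing_frac = 0),
    list(name = "allo", kind = "allometric", a = 1, b = b, sigma = sigma_allo,
         lambda = lambda, missing_frac = 0))
  for (r in seq_len(n_seeds)) {
    cfg <- synth_config(n_species = n_species, trait_specs = specs,
                        seed = seed_offset + r)
    d <- simulate_dataset(cfg)
    cov <- bm_covariance(d$tree)
    for (tr in c("inv", "allo")) {
      t1 <- suppressWarnings(type1_test(d$table, tr, n_mc = n_mc,
                                        seed = seed_offset + r, lenient = lenient))
      pl <- paired_log10(d$table, tr)
      ols <- ols_fit(pl$x, pl$y)
      pgls <- suppressWarnings(pgls_fit(pl$x, pl$y, cov, taxa = pl$species))
      t2 <- evaluate_type2(ols, pgls)
      row <- classify_trait(t1, t2, trait = tr)
      if (tr == "inv") inv_ok[r] <- isTRUE(row$type_I_II)
      else allo_ok[r] <- !isTRUE(row$type_I_II)
    }
  }
  list(invariant_correct_rate = mean(inv_ok),
       allometric_rejected_rate = mean(allo_ok),
       joint_correct_rate = mean(inv_ok & allo_ok),
       invariant_correct = inv_ok, allometric_rejected = allo_ok)
}

#' PGLS slope-recovery study
#'
#' Simulates allometric traits with a known exponent and phylogenetic signal
#' on fresh pure-birth trees and refits them by PGLS, recording the mean
#' slope bias and the empirical coverage of the 95% confidence interval.
#'
#' @param n_reps replicates.
#' @param n_species tips per tree.
#' @param b,lambda,sigma generating parameters.
#' @param seed_offset added to each replicate seed.
#' @return list with `mean_bias`, `ci_coverage`, `slopes`.
#' @export
slope_recovery_study <- function(n_reps = 200, n_species = 150, b = 0.3,
                                 lambda = 0.8, sigma = 0.1, seed_offset = 0) {
  slopes <- numeric(n_reps); covered <- logical(n_reps)
  spec <- list(name = "t", kind = "allometric", a = 1, b = b, sigma = sigma,
               lambda = lambda, missing_frac = 0)
  for (r in seq_len(n_reps)) {
    set.seed(seed_offset + r)
    tree <- simulate_yule_tree(n_species, 1)
    mass <- stats::setNames(stats::rnorm(n_species, 0.97, 0.76),
                            tree$tip.label)
    trv <- simulate_trait(tree, spec, mass)
    y <- log10(trv)
    cov <- bm_covariance(tree)
    f <- suppressWarnings(pgls_fit(mass[names(y)], y, cov, taxa = names(y)))
    slopes[r] <- f$slope
    covered[r] <- f$slope_ci[1] <= b && b <= f$slope_ci[2]
  }
  list(mean_bias = mean(slopes) - b, ci_coverage = mean(covered),
       slopes = slopes)
}

#' Dip-test calibration study
#'
#' Estimates the type-I error of the Monte-Carlo dip test at a given level
#' under the uniform null.
#'
#' @param n_reps number of null samples tested.
#' @param n sample size.
#' @param n_mc Monte-Carlo draws per test.
#' @param alpha nominal level.
#' @return list with `rejection_rate`, `n_reps`, `mc_se` (binomial SE at the
#'   nominal level).
#' @export
dip_calibration_study <- function(n_reps = 500, n = 50, n_mc = 2000,
                                  alpha = 0.05) {
  rej <- 0
  for (r in seq_len(n_reps)) {
    p <- dip_pvalue(stats::runif(n), n_mc = n_mc)$p
    if (p < alpha) rej <- rej + 1
  }
  list(rejection_rate = rej / n_reps, n_reps = n_reps,
       mc_se = sqrt(alpha * (1 - alpha) / n_reps))
}
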