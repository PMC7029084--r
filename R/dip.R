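#' Hartigan's dip statistic
#'
#' The dip is the smallest sup-norm distance between the empirical CDF of a
#' sample and the class of unimodal CDFs (convex up to the mode, concave
#' after it).  Large values indicate departure from unimodality.  The
#' statistic is invariant to monotone affine transforms of the data, lies in
#' `(0, 0.25]`, and is bounded below by `1/(2n)`.
#'
#' The computation solves, by bisection on the candidate distance, a
#' band-feasibility problem: at each distinct value the fitted CDF must pass
#' through a band around the empirical step, the left part must admit a
#' convex transversal (a greatest-convex-minorant condition on the band
#' corners), the right part a concave one (least concave majorant), and the
#' two sides must join at a candidate modal point.
#'
#' @param x numeric sample.
#' @param min_n smallest admissible sample size (default 4); smaller samples
#'   return `NA` with an `insufficient` attribute rather than an error so
#'   that screening loops can continue.
#' @return the dip statistic `D`, or `NA_real_` flagged `insufficient`.
#' @export
dip_statistic <- function(x, min_n = 4) {
  x <- x[!is.na(x)]
  if (length(x) < min_n)
    return(structure(NA_real_, insufficient = TRUE))
  dip_stat_cpp(as.numeric(x))
}

#' Monte-Carlo p-value for Hartigan's dip test
#'
#' The reference distribution of the dip under unimodality is taken, as is
#' conventional, from the uniform(0,1) null (the asymptotically least
#' favourable unimodal distribution).  The p-value is the continuity-corrected
#' proportion of `n_mc` uniform samples of size `n` whose dip reaches the
#' observed one: `p = (1 + #{D_null >= D}) / (n_mc + 1)`.
#'
#' @param x numeric sample.
#' @param n_mc number of null replicates (at least 1000).
#' @param seed optional integer seed applied via [set.seed()] for
#'   reproducibility; when `NULL` the current RNG stream is used.
#' @param min_n smallest admissible sample size.
#' @return object of class `dip_result`: list with `D`, `p`, `n`, `n_mc`,
#'   `seed`, and `insufficient`.
#' @export
dip_pvalue <- function(x, n_mc = 10000, seed = NULL, min_n = 4) {
  stopifnot(n_mc >= 1000)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < min_n)
    return(structure(list(D = NA_real_, p = NA_real_, n = n, n_mc = n_mc,
                          seed = seed, insufficient = TRUE),
                     class = "dip_result"))
  D <- dip_stat_cpp(as.numeric(x))
  if (!is.null(seed)) set.seed(seed)
  n_ge <- dip_null_count_ge_cpp(n, as.integer(n_mc), D)
  p <- (1 + n_ge) / (n_mc + 1)
  structure(list(D = D, p = p, n = n, n_mc = n_mc, seed = seed,
                 insufficient = FALSE),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  if (isTRUE(x$insufficient)) {
    cat("Dip test: insufficient sample (n =", x$n, ")\n")
  } else {
    cat(sprintf("Hartigan's dip test: D = %.4f, p = %.4f (n = %d, %d Monte-Carlo draws)\n",
                x$D, x$p, x$n, x$n_mc))
  }
  invisible(x)
}
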