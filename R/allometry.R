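#' Ordinary least-squares allometric fit (criteria 3 and 4)
#'
#' Fits log10(trait) = log10(a) + b * log10(mass) by OLS.  In the invariance
#' framework a coefficient of determination below 0.05 and a slope not
#' significantly different from zero both point to type II invariance.
#'
#' @param x numeric vector, log10 body mass.
#' @param y numeric vector, log10 trait, same length.
#' @param conf confidence level for the intervals (default 0.95).
#' @return object of class `ols_fit` with slope, intercept, their
#'   t-based confidence intervals, `r2`, `adj_r2`, `p_slope`, residual `df`
#'   and `n`.
#' @export
ols_fit <- function(x, y, conf = 0.95) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("ols_fit needs at least 3 complete pairs (got ", n, ")")
  if (stats::sd(x) == 0) stop("ols_fit: predictor is constant")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 slope_ci = unname(ci[2, ]), intercept_ci = unname(ci[1, ]),
                 r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
                 p_slope = sm$coefficients[2, 4],
                 df = fit$df.residual, n = n),
            class = "ols_fit")
}

# error covariance (up to sigma^2) at a given lambda
pgls_weight_matrix <- function(cov, lambda, weights_mode) {
  if (weights_mode == "depth") {
    # tip variances fixed proportional to root-to-tip depth: the standard
    # correction for noncontemporaneous tips on non-ultrametric trees
    W <- cov$V * lambda
    diag(W) <- cov$depths
  } else {
    C <- cov$V / sqrt(outer(cov$depths, cov$depths))
    W <- C * lambda
    diag(W) <- 1
  }
  W
}

# profile log-likelihood of the GLS model at fixed lambda
pgls_loglik <- function(lambda, X, y, cov, weights_mode, method) {
  n <- length(y); p <- ncol(X)
  W <- pgls_weight_matrix(cov, lambda, weights_mode)
  L <- tryCatch(chol(W), error = function(e)
    stop("singular phylogenetic covariance (near-duplicate taxa?)", call. = FALSE))
  logdetW <- 2 * sum(log(diag(L)))
  Xs <- backsolve(L, X, transpose = TRUE)
  ys <- backsolve(L, y, transpose = TRUE)
  XtX <- crossprod(Xs)
  beta <- solve(XtX, crossprod(Xs, ys))
  r <- ys - Xs %*% beta
  rss <- sum(r^2)
  if (method == "REML") {
    s2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2) + logdetW +
                    determinant(XtX, logarithm = TRUE)$modulus + (n - p))
  } else {
    s2 <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2) + logdetW + n)
  }
  list(ll = as.numeric(ll), beta = beta, rss = rss, XtX = XtX)
}

#' Phylogenetic generalized least-squares fit with Pagel's lambda
#'
#' GLS regression of log10(trait) on log10(mass) whose error covariance is
#' sigma^2 * W(lambda), with W(lambda) the Brownian-motion covariance of the
#' pruned tree, off-diagonals scaled by Pagel's lambda.  In the default
#' `"depth"` weights mode the tip variances are fixed proportional to the
#' root-to-tip depths, which corrects for noncontemporaneous tips on
#' non-ultrametric trees; `"uniform"` standardizes the matrix to a
#' correlation so that all tips carry equal residual variance (on an
#' ultrametric tree the two modes coincide).
#'
#' lambda is estimated by maximizing the (profile) likelihood on a 51-point
#' grid over `lambda_bounds` followed by golden-section refinement; ML is
#' the default criterion, REML is available.  Inference on the coefficients
#' is conditional on the estimated lambda, with t intervals on `n - p`
#' degrees of freedom.
#'
#' @param x log10 body-mass vector, or `NULL` for an intercept-only model.
#' @param y log10 trait vector.
#' @param cov a [bm_covariance()] object covering all sampled taxa.
#' @param taxa taxon names aligning `y` with `cov` (defaults to `names(y)`).
#' @param weights_mode `"depth"` (default) or `"uniform"`.
#' @param lambda fixed value of lambda; `NULL` (default) estimates it.
#' @param lambda_bounds search interval, default `c(0, 1)`.
#' @param method `"ML"` (default) or `"REML"`.
#' @param conf confidence level.
#' @return object of class `pgls_fit` with coefficients, intervals,
#'   `p_slope`, `lambda`, `loglik` and `n`.
#' @export
pgls_fit <- function(x, y, cov, taxa = NULL,
                     weights_mode = c("depth", "uniform"),
                     lambda = NULL, lambda_bounds = c(0, 1),
                     method = c("ML", "REML"), conf = 0.95) {
  weights_mode <- match.arg(weights_mode)
  method <- match.arg(method)
  if (is.null(taxa)) taxa <- names(y)
  if (is.null(taxa)) stop("supply `taxa` or a named `y` to align with the covariance")
  ok <- if (is.null(x)) !is.na(y) else !is.na(x) & !is.na(y)
  y <- y[ok]; taxa <- taxa[ok]
  if (!is.null(x)) x <- x[ok]
  n <- length(y)
  if (n < 3) stop("pgls_fit needs at least 3 complete pairs (got ", n, ")")
  cov <- restrict_cov(cov, taxa)
  X <- if (is.null(x)) matrix(1, n, 1) else cbind(1, x)
  colnames(X) <- if (is.null(x)) "intercept" else c("intercept", "slope")

  if (is.null(lambda)) {
    grid <- seq(lambda_bounds[1], lambda_bounds[2], length.out = 51)
    lls <- vapply(grid, function(l)
      pgls_loglik(l, X, y, cov, weights_mode, method)$ll, 0)
    i <- which.max(lls)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- stats::optimize(function(l)
      pgls_loglik(l, X, y, cov, weights_mode, method)$ll,
      interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
    lambda_hat <- opt$maximum
    if (lls[i] > opt$objective) lambda_hat <- grid[i]
    if (min(abs(lambda_hat - lambda_bounds)) < 1e-4)
      warning("lambda estimate at a search bound (", signif(lambda_hat, 3), ")",
              call. = FALSE)
  } else {
    lambda_hat <- lambda
  }
  fit <- pgls_loglik(lambda_hat, X, y, cov, weights_mode, method)
  p <- ncol(X)
  df <- n - p
  s2 <- fit$rss / df  # conditional-on-lambda residual variance for inference
  vc <- s2 * solve(fit$XtX)
  se <- sqrt(diag(vc))
  tq <- stats::qt(1 - (1 - conf) / 2, df)
  beta <- as.numeric(fit$beta)
  ci <- cbind(beta - tq * se, beta + tq * se)
  slope <- if (p == 2) beta[2] else NA_real_
  p_slope <- if (p == 2) 2 * stats::pt(-abs(beta[2] / se[2]), df) else NA_real_
  structure(list(slope = slope, intercept = beta[1],
                 slope_ci = if (p == 2) ci[2, ] else c(NA_real_, NA_real_),
                 intercept_ci = ci[1, ],
                 p_slope = p_slope, lambda = lambda_hat,
                 loglik = fit$ll, n = n, df = df,
                 weights_mode = weights_mode, method = method,
                 lambda_fixed = !is.null(lambda)),
            class = "pgls_fit")
}

#' Type II invariance verdict from OLS and PGLS fits
#'
#' A trait is called type II invariant only when the OLS coefficient of
#' determination is below `r2_max` *and* both the OLS and the PGLS slope are
#' nonsignificant -- the conservative three-way conjunction.  When no usable
#' tree is available the PGLS component is `NA`; by default this blocks the
#' verdict, unless `degraded = TRUE` allows an OLS-only verdict (flagged in
#' the result).
#'
#' @param ols an [ols_fit()] result (or `NULL`).
#' @param pgls a [pgls_fit()] result or `NULL`.
#' @param alpha slope significance level (default 0.05).
#' @param r2_max R-squared threshold (default 0.05).
#' @param degraded allow an OLS-only verdict when PGLS is unavailable.
#' @return object of class `type2_verdict`.
#' @export
evaluate_type2 <- function(ols, pgls, alpha = 0.05, r2_max = 0.05,
                           degraded = FALSE) {
  pass_r2 <- if (is.null(ols)) NA else ols$r2 < r2_max
  pass_ols <- if (is.null(ols)) NA else ols$p_slope >= alpha
  pass_pgls <- if (is.null(pgls)) NA else pgls$p_slope >= alpha
  if (is.null(ols)) {
    verdict <- NA
  } else if (is.null(pgls)) {
    verdict <- if (degraded) isTRUE(pass_r2) && isTRUE(pass_ols) else NA
  } else {
    verdict <- isTRUE(pass_r2) && isTRUE(pass_ols) && isTRUE(pass_pgls)
  }
  structure(list(pass_r2 = pass_r2, pass_ols_slope = pass_ols,
                 pass_pgls_slope = pass_pgls, verdict_type2 = verdict,
                 degraded = is.null(pgls) && degraded,
                 alpha = alpha, r2_max = r2_max),
            class = "type2_verdict")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS: slope %.3f (%.3f, %.3f), intercept %.3f, R2 = %.3f, p = %.3g, n = %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$intercept, x$r2,
              x$p_slope, x$n))
  invisible(x)
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS (%s weights, %s): slope %.3f (%.3f, %.3f), lambda = %.2f, p = %.3g, n = %d\n",
              x$weights_mode, x$method, x$slope, x$slope_ci[1], x$slope_ci[2],
              x$lambda, x$p_slope, x$n))
  invisible(x)
}
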