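test_that("ols_fit reproduces the normal equations by hand", {
  # points (0,0),(1,1),(2,3): slope 1.5, intercept -1/6, r2 = 27/28
  f <- ols_fit(c(0, 1, 2), c(0, 1, 3))
  expect_equal(f$slope, 1.5)
  expect_equal(f$intercept, -1 / 6, tolerance = 1e-12)
  expect_equal(f$r2, 27 / 28, tolerance = 1e-12)
  # noiseless line recovered exactly
  x <- c(-1, 0, 2, 5, 7)
  f2 <- suppressWarnings(ols_fit(x, 0.25 * x + 2))
  expect_equal(f2$slope, 0.25, tolerance = 1e-10)
  expect_equal(f2$intercept, 2, tolerance = 1e-10)
  expect_equal(f2$r2, 1)
  expect_error(ols_fit(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(ols_fit(c(1, 2), c(1, 2)), "at least 3")
})

test_that("ols invariants: r2 = squared correlation, CI/p duality", {
  set.seed(14)
  for (r in 1:15) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- 0.2 * x + rnorm(n, 0, runif(1, .1, 2))
    f <- ols_fit(x, y)
    expect_equal(f$r2, cor(x, y)^2, tolerance = 1e-12)
    expect_lte(f$adj_r2, f$r2)
    expect_true(f$slope_ci[1] <= f$slope && f$slope <= f$slope_ci[2])
    inside <- f$slope_ci[1] <= 0 && 0 <= f$slope_ci[2]
    expect_identical(f$p_slope >= 0.05, inside)
  }
})

test_that("intercept-only GLS on the worked 3-taxon tree gives mean 3", {
  cov <- bm_covariance(make_worked_tree())
  y <- c(A = 2, B = 4, C = 3)
  f <- pgls_fit(NULL, y, cov, lambda = 1)
  # by hand: V = [[2,1,0],[1,2,0],[0,0,2]]; (1'V^-1 y)/(1'V^-1 1) = 3.5/(7/6) = 3
  expect_equal(f$intercept, 3, tolerance = 1e-10)
})

test_that("PGLS with lambda 0 and uniform weights collapses to OLS", {
  set.seed(23)
  for (r in 1:10) {
    n <- sample(8:40, 1)
    tree <- simulate_yule_tree(n, 1, tip_jitter_sd = sample(c(0, .3), 1))
    cov <- bm_covariance(tree)
    x <- setNames(rnorm(n), tree$tip.label)
    y <- 0.3 * x + rnorm(n, 0, 0.3)
    names(y) <- names(x)
    g <- pgls_fit(x, y, cov, weights_mode = "uniform", lambda = 0)
    o <- ols_fit(x, y)
    expect_equal(g$slope, o$slope, tolerance = 1e-8)
    expect_equal(g$intercept, o$intercept, tolerance = 1e-8)
  }
})

test_that("on a star tree PGLS equals OLS for any lambda", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1,E:1,F:1,G:1,H:1);")
  cov <- bm_covariance(star)
  set.seed(3)
  x <- setNames(rnorm(8), star$tip.label)
  y <- 1 - 0.5 * x + rnorm(8, 0, 0.2); names(y) <- names(x)
  g <- pgls_fit(x, y, cov, weights_mode = "uniform", lambda = 0.7)
  o <- ols_fit(x, y)
  expect_equal(g$slope, o$slope, tolerance = 1e-8)
  expect_equal(g$intercept, o$intercept, tolerance = 1e-8)
})

test_that("profile likelihood is maximized at the estimated lambda", {
  set.seed(31)
  tree <- simulate_yule_tree(60, 1)
  cov <- bm_covariance(tree)
  mass <- setNames(rnorm(60, 1, 0.7), tree$tip.label)
  tr <- simulate_trait(tree, list(name = "t", kind = "allometric", a = 1,
                                  b = 0.3, sigma = 0.15, lambda = 0.6,
                                  missing_frac = 0), mass)
  y <- log10(tr)
  f <- pgls_fit(mass, y, cov, taxa = names(y))
  ll_at <- function(l) pgls_fit(mass, y, cov, taxa = names(y), lambda = l)$loglik
  expect_gte(f$loglik, ll_at(0) - 1e-8)
  expect_gte(f$loglik, ll_at(1) - 1e-8)
})

test_that("PGLS agrees with the nlme/corPagel reference implementation", {
  skip_if_not_installed("nlme")
  library(nlme)
  set.seed(42)
  tree <- simulate_yule_tree(40, 1, tip_jitter_sd = 0.4)  # non-ultrametric
  cov <- bm_covariance(tree)
  mass <- setNames(rnorm(40, 1, 0.7), tree$tip.label)
  tr <- simulate_trait(tree, list(name = "t", kind = "allometric", a = 1,
                                  b = 0.3, sigma = 0.15, lambda = 0.7,
                                  missing_frac = 0), mass)
  y <- log10(tr); x <- mass[names(y)]
  dat <- data.frame(x = x, y = y, sp = names(y), depth = cov$depths[names(y)])
  rownames(dat) <- dat$sp
  # fixed lambda: coefficients must agree to high precision
  g_fix <- gls(y ~ x, data = dat,
               correlation = ape::corPagel(0.7, phy = tree, form = ~sp,
                                           fixed = TRUE),
               weights = varFixed(~depth), method = "ML")
  mine_fix <- pgls_fit(x, y, cov, taxa = names(y), lambda = 0.7)
  expect_equal(mine_fix$intercept, unname(coef(g_fix)[1]), tolerance = 1e-6)
  expect_equal(mine_fix$slope, unname(coef(g_fix)[2]), tolerance = 1e-6)
  # estimated lambda: ML optimum and inference should coincide
  g_ml <- gls(y ~ x, data = dat,
              correlation = ape::corPagel(0.5, phy = tree, form = ~sp),
              weights = varFixed(~depth), method = "ML")
  mine <- pgls_fit(x, y, cov, taxa = names(y))
  lam_nlme <- unname(coef(g_ml$modelStruct$corStruct, unconstrained = FALSE))
  expect_equal(mine$lambda, lam_nlme, tolerance = 1e-3)
  expect_equal(mine$slope, unname(coef(g_ml)[2]), tolerance = 1e-5)
  tt <- summary(g_ml)$tTable
  expect_equal(mine$p_slope, tt["x", "p-value"], tolerance = 1e-5)
})

test_that("evaluate_type2 applies the three-way conjunction", {
  mk_ols <- function(r2, p) structure(list(r2 = r2, p_slope = p), class = "ols_fit")
  mk_pgls <- function(p) structure(list(p_slope = p), class = "pgls_fit")
  v <- evaluate_type2(mk_ols(0.01, 0.7), mk_pgls(0.9))
  expect_true(v$verdict_type2)
  expect_false(evaluate_type2(mk_ols(0.18, 0.001), mk_pgls(0.9))$verdict_type2)
  expect_false(evaluate_type2(mk_ols(0.04, 0.03), mk_pgls(0.9))$verdict_type2)
  # missing PGLS blocks the verdict unless degraded mode is allowed
  v_na <- evaluate_type2(mk_ols(0.01, 0.7), NULL)
  expect_true(is.na(v_na$verdict_type2))
  v_deg <- evaluate_type2(mk_ols(0.01, 0.7), NULL, degraded = TRUE)
  expect_true(v_deg$verdict_type2)
  expect_true(v_deg$degraded)
})
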