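test_that("yule trees are reproducible, correctly sized, ultrametric by default", {
  t1 <- simulate_yule_tree(20, 1, seed = 9)
  t2 <- simulate_yule_tree(20, 1, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 20)
  expect_equal(t1$Nnode, 19)                 # n-1 internal nodes
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  t3 <- simulate_yule_tree(20, 1, seed = 9, tip_jitter_sd = 0.5)
  expect_false(ape::is.ultrametric(t3, tol = 1e-4))
  t4 <- simulate_yule_tree(2, 1, seed = 1)
  expect_equal(ape::Ntip(t4), 2)             # a single cherry
})

test_that("noiseless traits follow the power law exactly", {
  tree <- simulate_yule_tree(12, 1, seed = 4)
  mass <- stats::setNames(rnorm(12, 1, 0.5), tree$tip.label)
  tr <- simulate_trait(tree, list(name = "t", kind = "allometric", a = 1,
                                  b = 0.5, sigma = 0, lambda = 0.8,
                                  missing_frac = 0), mass)
  expect_equal(unname(log10(tr)), unname(0.5 * mass), tolerance = 1e-10)
  inv <- simulate_trait(tree, list(name = "t", kind = "invariant", a = 30,
                                   b = 0, sigma = 0, lambda = 0,
                                   missing_frac = 0), mass)
  expect_equal(unname(inv), rep(30, 12))
})

test_that("body-mass sample moments match the configuration", {
  cfg <- synth_config(n_species = 400, mass_log_mean = 0.97,
                      mass_log_sd = 0.76, seed = 31)
  d <- simulate_dataset(cfg)
  lm10 <- log10(d$table$body_mass)
  se_mean <- 0.76 / sqrt(400)
  expect_lt(abs(mean(lm10) - 0.97), 3 * se_mean)
  se_sd <- 0.76 / sqrt(2 * 399)
  expect_lt(abs(sd(lm10) - 0.76), 3 * se_sd)
  expect_setequal(d$table$species, d$tree$tip.label)
  expect_named(d$truth, vapply(cfg$trait_specs, `[[`, "", "name"))
})

test_that("missingness is reproducible, binomial in count, and flags tiny remainders", {
  cfg <- synth_config(n_species = 1000, seed = 8)
  d <- simulate_dataset(cfg)
  m1 <- apply_missingness(d$table, c(invariant_trait = 0.5), seed = 3)
  m2 <- apply_missingness(d$table, c(invariant_trait = 0.5), seed = 3)
  expect_identical(m1$invariant_trait, m2$invariant_trait)
  n_masked <- sum(is.na(m1$invariant_trait))
  expect_true(n_masked >= 420 && n_masked <= 580)  # P(outside) < 1e-3
  m0 <- apply_missingness(d$table, c(invariant_trait = 0), seed = 3)
  expect_identical(m0$invariant_trait, d$table$invariant_trait)
  expect_warning(
    apply_missingness(trait_table(
      data.frame(species = paste0("s", 1:4), group = "G",
                 body_mass = 1:4, tr = c(1, 2, 3, 4)),
      "tr", c(body_mass = "g", tr = "u")), c(tr = 0.9), seed = 42),
    "fewer than 3")
})

test_that("bimodal traits are rejected by the dip test at 5-sigma separation", {
  # centres 5 sigma apart, n = 150 tips
  reps <- 20; hits <- 0
  for (r in seq_len(reps)) {
    cfg <- synth_config(
      n_species = 150, seed = 100 + r,
      trait_specs = list(list(name = "bim", kind = "bimodal", a = 10,
                              a2 = 10^(1 + 5 * 0.1), b = 0, sigma = 0.1,
                              lambda = 0, missing_frac = 0)))
    d <- simulate_dataset(cfg)
    p <- dip_pvalue(log10(d$table$bim), n_mc = 1000, seed = r)$p
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})
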