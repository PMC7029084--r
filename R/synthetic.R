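#' Configuration for the synthetic trait generator
#'
#' Bundles the ground-truth parameters for a simulated comparative dataset:
#' a pure-birth tree, log-normally distributed body masses, and a set of
#' trait specifications.  Each trait is one of three kinds:
#' \describe{
#'   \item{allometric}{`log10 T = log10 a + b log10 M + eps`, with `eps`
#'     multivariate normal, covariance `sigma^2` times the Pagel-lambda
#'     transform of the Brownian-motion covariance normalized to unit
#'     root-to-tip depth (so `sigma` is the tip-level SD whatever the tree
#'     height).}
#'   \item{invariant}{`log10 T ~ Normal(log10 a, sigma^2)` i.i.d.; no mass
#'     or phylogeny dependence.}
#'   \item{bimodal}{an equal mixture of two invariant components centred at
#'     `a` and `a2` (raw scale).}
#' }
#'
#' @param n_species number of tips (>= 4).
#' @param birth_rate per-lineage speciation rate of the pure-birth tree.
#' @param mass_log_mean,mass_log_sd mean and SD of log10 body mass (grams).
#' @param trait_specs list of trait specifications; each a list with `name`,
#'   `kind` (`"allometric"`, `"invariant"`, `"bimodal"`), `a`, `b`, `sigma`,
#'   `lambda`, `missing_frac`, and `a2` for bimodal traits.
#' @param tip_jitter_sd lognormal SD multiplied onto terminal branches to
#'   produce a non-ultrametric tree (0 = ultrametric).
#' @param seed integer seed.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_species = 200, birth_rate = 1,
                         mass_log_mean = 0.97, mass_log_sd = 0.76,
                         trait_specs = default_trait_specs(),
                         tip_jitter_sd = 0, seed = 1) {
  stopifnot(n_species >= 4, birth_rate > 0, mass_log_sd >= 0)
  for (sp in trait_specs) {
    stopifnot(sp$kind %in% c("allometric", "invariant", "bimodal"),
              sp$sigma >= 0, sp$missing_frac >= 0, sp$missing_frac < 1)
    if (!is.null(sp$lambda)) stopifnot(sp$lambda >= 0, sp$lambda <= 1)
  }
  structure(list(n_species = n_species, birth_rate = birth_rate,
                 mass_log_mean = mass_log_mean, mass_log_sd = mass_log_sd,
                 trait_specs = trait_specs, tip_jitter_sd = tip_jitter_sd,
                 seed = seed),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_trait_specs <- function() {
  list(
    list(name = "invariant_trait", kind = "invariant", a = 30, b = 0,
         sigma = 0.05, lambda = 0, missing_frac = 0),
    list(name = "allometric_trait", kind = "allometric", a = 1, b = 0.4,
         sigma = 0.1, lambda = 0.8, missing_frac = 0),
    list(name = "bimodal_trait", kind = "bimodal", a = 10, a2 = 10^(1 + 0.5),
         b = 0, sigma = 0.1, lambda = 0, missing_frac = 0)
  )
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Wraps [ape::rphylo()] with optional lognormal jitter on the terminal
#' branches, which breaks ultrametricity and exercises the
#' noncontemporaneous-tip weighting in the PGLS module.
#'
#' @param n_species number of tips.
#' @param birth_rate speciation rate.
#' @param seed optional integer seed.
#' @param tip_jitter_sd lognormal sigma of the multiplicative terminal-branch
#'   jitter (0 disables it).
#' @return an [ape::phylo] tree with tips `s1..sN`.
#' @export
simulate_yule_tree <- function(n_species, birth_rate = 1, seed = NULL,
                               tip_jitter_sd = 0) {
  stopifnot(n_species >= 2)
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  tree$tip.label <- paste0("s", seq_len(n_species))
  if (tip_jitter_sd > 0) {
    term <- match(seq_len(n_species), tree$edge[, 2])
    tree$edge.length[term] <- tree$edge.length[term] *
      exp(stats::rnorm(n_species, 0, tip_jitter_sd))
  }
  tree
}

#' Simulate one trait on a phylogeny
#'
#' @param tree an [ape::phylo] tree.
#' @param spec one trait specification (see [synth_config()]).
#' @param mass_log10 named vector of log10 body masses for all tips.
#' @return named vector of trait values on the raw (10^) scale.
#' @export
simulate_trait <- function(tree, spec, mass_log10) {
  tips <- tree$tip.label
  if (!all(tips %in% names(mass_log10)))
    stop("mass_log10 must be named and cover every tip")
  mass_log10 <- mass_log10[tips]
  n <- length(tips)
  logT <- switch(spec$kind,
    allometric = {
      cov <- bm_covariance(tree)
      Vn <- cov$V / max(cov$depths)   # unit-depth normalization
      diag_n <- diag(Vn)
      W <- Vn * spec$lambda
      diag(W) <- diag_n
      eps <- MASS::mvrnorm(1, mu = rep(0, n), Sigma = spec$sigma^2 * W)
      log10(spec$a) + spec$b * mass_log10 + eps
    },
    invariant = log10(spec$a) + stats::rnorm(n, 0, spec$sigma),
    bimodal = {
      comp <- stats::runif(n) < 0.5
      centre <- ifelse(comp, log10(spec$a), log10(spec$a2))
      centre + stats::rnorm(n, 0, spec$sigma)
    },
    stop("unknown trait kind: ", spec$kind))
  stats::setNames(10^as.numeric(logT), tips)
}

#' Mask trait values at random
#'
#' Independently masks each entry of the named trait columns at the stated
#' per-trait rate; the realized number of masked cells is binomial.
#'
#' @param table a [trait_table()].
#' @param missing_frac named numeric vector of per-trait missingness rates
#'   in `[0, 1)`.
#' @param seed optional integer seed.
#' @return the masked table.
#' @export
apply_missingness <- function(table, missing_frac, seed = NULL) {
  stopifnot(all(missing_frac >= 0), all(missing_frac < 1))
  if (!is.null(seed)) set.seed(seed)
  df <- as.data.frame(table)
  for (tr in names(missing_frac)) {
    if (!tr %in% names(df)) stop("unknown trait: ", tr)
    if (missing_frac[[tr]] == 0) next
    mask <- stats::runif(nrow(df)) < missing_frac[[tr]]
    df[[tr]][mask] <- NA_real_
    if (sum(!is.na(df[[tr]])) < 3)
      warning("trait '", tr, "' left with fewer than 3 records", call. = FALSE)
  }
  trait_table(df, traits = attr(table, "traits"), units = attr(table, "units"))
}

#' Generate a complete synthetic dataset
#'
#' Simulates the tree, i.i.d. lognormal body masses (the default isolates
#' criterion behaviour from mass phylogenetic signal), every configured
#' trait, and the per-trait missingness, and returns the pieces together
#' with the ground truth.
#'
#' @param config a [synth_config()].
#' @return list with `tree`, `table` (a [trait_table()] with group label
#'   `"Synthetic"`), and `truth` (per-trait generating parameters).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  tree <- simulate_yule_tree(config$n_species, config$birth_rate,
                             tip_jitter_sd = config$tip_jitter_sd)
  mass_log10 <- stats::setNames(
    stats::rnorm(config$n_species, config$mass_log_mean, config$mass_log_sd),
    tree$tip.label)
  df <- data.frame(species = tree$tip.label, group = "Synthetic",
                   body_mass = 10^mass_log10, stringsAsFactors = FALSE)
  units <- c(body_mass = "g")
  for (sp in config$trait_specs) {
    df[[sp$name]] <- unname(simulate_trait(tree, sp, mass_log10))
    units[sp$name] <- "simulated"
  }
  traits <- vapply(config$trait_specs, `[[`, "", "name")
  tab <- trait_table(df, traits = traits, units = units)
  mf <- stats::setNames(vapply(config$trait_specs, `[[`, 0, "missing_frac"), traits)
  if (any(mf > 0)) tab <- apply_missingness(tab, mf)
  truth <- lapply(config$trait_specs, function(sp)
    sp[intersect(names(sp), c("name", "kind", "a", "a2", "b", "sigma",
                              "lambda", "missing_frac"))])
  names(truth) <- traits
  list(tree = tree, table = tab, truth = truth)
}
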