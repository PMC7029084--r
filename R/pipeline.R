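#' Run configuration for the invariance pipeline
#'
#' Collects every input and threshold for a full run.  Either in-memory
#' objects (`table`, `tree`) or file paths (`traits_path`, `tree_path`) may
#' be supplied; paths are read with [read_trait_table()] / [read_newick()].
#'
#' @param table a [trait_table()], or `NULL` to read from `traits_path`.
#' @param tree an [ape::phylo] tree, or `NULL`; without a tree the run is
#'   OLS-only and PGLS columns are reported as unavailable.
#' @param traits_path,tree_path,schema file inputs (see [read_trait_table()]).
#' @param groups list of [group_spec()]s; default: one group per distinct
#'   group label in the table.
#' @param traits trait names to analyse; default: all traits in the table.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param alpha significance level shared by the dip, slope and correlation
#'   tests.
#' @param r2_max R-squared threshold for criterion on determination.
#' @param coverage_pass,coverage_marginal coverage thresholds (percent).
#' @param n_mc dip-test Monte-Carlo replicates.
#' @param seed master seed; per-trait dip seeds are derived from it.
#' @param lambda_bounds PGLS lambda search interval.
#' @param weights_mode PGLS weights (`"depth"` or `"uniform"`).
#' @param lenient count marginal coverage toward type I.
#' @param degraded allow OLS-only type II verdicts when no tree is usable.
#' @param min_n_regression fewest complete pairs for which a regression is
#'   reported (default 8; smaller samples appear as unavailable).
#' @param sma_min_n fewest complete cases for an SMA pair fit.
#' @export
run_config <- function(table = NULL, tree = NULL, traits_path = NULL,
                       tree_path = NULL, schema = NULL, groups = NULL,
                       traits = NULL, out_dir = NULL, alpha = 0.05,
                       r2_max = 0.05, coverage_pass = 95,
                       coverage_marginal = 94, n_mc = 10000, seed = 1,
                       lambda_bounds = c(0, 1),
                       weights_mode = "depth", lenient = FALSE,
                       degraded = FALSE, min_n_regression = 8, sma_min_n = 5) {
  if (is.null(table)) {
    stopifnot(!is.null(traits_path), !is.null(schema))
    table <- read_trait_table(traits_path, schema)
  }
  if (is.null(tree) && !is.null(tree_path)) tree <- read_newick(tree_path)
  if (is.null(traits)) traits <- attr(table, "traits")
  if (is.null(groups)) {
    labs <- unique(stats::na.omit(table$group))
    groups <- lapply(labs, function(g) group_spec(g, g))
  }
  structure(list(table = table, tree = tree, groups = groups, traits = traits,
                 out_dir = out_dir, alpha = alpha, r2_max = r2_max,
                 coverage_pass = coverage_pass,
                 coverage_marginal = coverage_marginal, n_mc = n_mc,
                 seed = seed, lambda_bounds = lambda_bounds,
                 weights_mode = weights_mode, lenient = lenient,
                 degraded = degraded, min_n_regression = min_n_regression,
                 sma_min_n = sma_min_n),
            class = "run_config")
}

#' Run the five-criterion invariance analysis
#'
#' For every analysis group and trait this computes the type I battery
#' (variance ratio, dip test, 2 SD coverage), the OLS and PGLS allometric
#' fits, the type II verdict, and the classification grid, plus the SMA
#' isometry scan over trait pairs.  Per-trait failures are logged and the
#' run continues.  When `out_dir` is set, per-group TSV tables (type I
#' statistics, regression statistics, SMA pairs), the verdict grid, a JSON
#' bundle of every statistic, and a plain-text decision log are written;
#' reruns with an identical configuration are byte-identical.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of per-group results: `type1`, `ols`, `pgls`,
#'   `type2`, `report`, `sma`, and the run `log`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, paste0(...))
  say("seed: ", config$seed, "; alpha: ", config$alpha,
      "; r2_max: ", config$r2_max, "; n_mc: ", config$n_mc)
  cov <- if (!is.null(config$tree)) bm_covariance(config$tree) else NULL
  results <- list()
  for (gi in seq_along(config$groups)) {
    gs <- config$groups[[gi]]
    sub <- withCallingHandlers(subset_group(config$table, gs),
                               warning = function(w) {
                                 say("warning [", gs$name, "]: ", conditionMessage(w))
                                 invokeRestart("muffleWarning")
                               })
    say("group ", gs$name, ": ", nrow(sub), " species")
    g <- list(group = gs$name, type1 = list(), ols = list(), pgls = list(),
              type2 = list(), rows = list())
    for (ti in seq_along(config$traits)) {
      tr <- config$traits[ti]
      seed_tr <- (config$seed * 1000L + gi * 100L + ti) %% .Machine$integer.max
      res <- tryCatch({
        t1 <- suppressWarnings(type1_test(
          sub, tr, alpha = config$alpha, n_mc = config$n_mc, seed = seed_tr,
          lenient = config$lenient, coverage_pass = config$coverage_pass,
          coverage_marginal = config$coverage_marginal))
        pl <- paired_log10(sub, tr)
        ols <- pgls <- NULL
        if (pl$n >= config$min_n_regression) {
          ols <- ols_fit(pl$x, pl$y)
          if (!is.null(cov)) {
            in_tree <- pl$species %in% cov$taxa
            if (sum(!in_tree) > 0)
              say("group ", gs$name, ", trait ", tr, ": ", sum(!in_tree),
                  " species not in tree, excluded from PGLS")
            if (sum(in_tree) >= config$min_n_regression) {
              pgls <- suppressWarnings(pgls_fit(
                pl$x[in_tree], pl$y[in_tree], cov, taxa = pl$species[in_tree],
                weights_mode = config$weights_mode,
                lambda_bounds = config$lambda_bounds))
            } else say("group ", gs$name, ", trait ", tr,
                       ": too few species in tree for PGLS")
          }
        } else {
          say("group ", gs$name, ", trait ", tr, ": sample too small for ",
              "regression (n = ", pl$n, " < ", config$min_n_regression, ")")
        }
        t2 <- evaluate_type2(ols, pgls, alpha = config$alpha,
                             r2_max = config$r2_max,
                             degraded = config$degraded)
        row <- classify_trait(t1, t2, trait = tr)
        say("group ", gs$name, ", trait ", tr, ": c1=", row$marks[["criterion1"]],
            " unimodal=", row$marks[["unimodality"]],
            " coverage=", row$marks[["coverage"]],
            " olsSlope=", row$marks[["ols_slope"]],
            " pglsSlope=", row$marks[["pgls_slope"]],
            " r2=", row$marks[["r2"]],
            " typeI=", verdict_symbol(row$type_I),
            " typeII=", verdict_symbol(row$type_II),
            " typeI+II=", verdict_symbol(row$type_I_II))
        list(t1 = t1, ols = ols, pgls = pgls, t2 = t2, row = row)
      }, error = function(e) {
        say("ERROR group ", gs$name, ", trait ", tr, ": ", conditionMessage(e))
        NULL
      })
      if (is.null(res)) next
      g$type1[[tr]] <- res$t1; g$ols[[tr]] <- res$ols
      g$pgls[[tr]] <- res$pgls; g$type2[[tr]] <- res$t2
      g$rows[[tr]] <- res$row
    }
    g$report <- if (length(g$rows)) build_report(g$rows, gs$name) else NULL
    g$sma <- if (length(config$traits) >= 2)
      tryCatch(scan_pairs(sub, config$traits, alpha = config$alpha,
                          min_n = config$sma_min_n),
               error = function(e) { say("ERROR SMA ", gs$name, ": ",
                                         conditionMessage(e)); NULL })
      else NULL
    if (!is.null(g$sma))
      for (nm in names(g$sma$skipped))
        say("group ", gs$name, ", SMA pair ", nm, " skipped: ",
            g$sma$skipped[[nm]]$reason)
    results[[gs$name]] <- g
  }
  out <- list(groups = results, config_summary = config_summary(config),
              log = log_lines)
  if (!is.null(config$out_dir)) write_outputs(out, config)
  invisible(out)
}

config_summary <- function(config) {
  list(alpha = config$alpha, r2_max = config$r2_max,
       coverage_pass = config$coverage_pass,
       coverage_marginal = config$coverage_marginal, n_mc = config$n_mc,
       seed = config$seed, lambda_bounds = config$lambda_bounds,
       weights_mode = config$weights_mode, lenient = config$lenient,
       degraded = config$degraded,
       min_n_regression = config$min_n_regression,
       sma_min_n = config$sma_min_n,
       traits = config$traits,
       groups = lapply(config$groups, function(g)
         list(name = g$name, members = g$member_groups)))
}

num_or_na <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) NA_real_ else x

write_outputs <- function(out, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(x, d = 4) ifelse(is.na(x), "NA", formatC(x, digits = d, format = "g"))
  for (gname in names(out$groups)) {
    g <- out$groups[[gname]]
    slug <- gsub("[^A-Za-z0-9]+", "_", gname)
    # type I statistics table
    t1rows <- lapply(names(g$type1), function(tr) {
      t1 <- g$type1[[tr]]
      data.frame(trait = tr,
                 variance = num_or_na(t1$variance_ratio$trait_var),
                 mass_var_over_trait_var = num_or_na(t1$variance_ratio$ratio),
                 dip_D = num_or_na(if (!is.null(t1$dip)) t1$dip$D else NA),
                 dip_p = num_or_na(if (!is.null(t1$dip)) t1$dip$p else NA),
                 pct_within_2sd = num_or_na(t1$coverage))
    })
    if (length(t1rows))
      utils::write.table(do.call(rbind, t1rows),
                         file.path(config$out_dir, paste0("type1_", slug, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
    # regression table (OLS + PGLS rows)
    regrows <- list()
    for (tr in names(g$rows)) {
      for (kind in c("ols", "pgls")) {
        f <- g[[kind]][[tr]]
        regrows[[paste(tr, kind)]] <- data.frame(
          trait = tr, model = toupper(kind),
          df = if (is.null(f)) NA else f$df,
          r2 = if (is.null(f) || kind == "pgls") NA else f$r2,
          adj_r2 = if (is.null(f) || kind == "pgls") NA else f$adj_r2,
          p = if (is.null(f)) NA else f$p_slope,
          slope = if (is.null(f)) NA else f$slope,
          slope_lo = if (is.null(f)) NA else f$slope_ci[1],
          slope_hi = if (is.null(f)) NA else f$slope_ci[2],
          intercept = if (is.null(f)) NA else f$intercept,
          intercept_lo = if (is.null(f)) NA else f$intercept_ci[1],
          intercept_hi = if (is.null(f)) NA else f$intercept_ci[2],
          lambda = if (is.null(f) || kind == "ols") NA else f$lambda)
      }
    }
    if (length(regrows))
      utils::write.table(do.call(rbind, regrows),
                         file.path(config$out_dir, paste0("regression_", slug, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
    # SMA pair scan
    if (!is.null(g$sma)) {
      smarows <- lapply(names(g$sma$fits), function(nm) {
        e <- g$sma$fits[[nm]]
        data.frame(pair = nm, n = e$n, r2 = e$fit$r2, p = e$fit$p_corr,
                   slope = e$fit$slope, slope_lo = e$fit$slope_ci[1],
                   slope_hi = e$fit$slope_ci[2], intercept = e$fit$intercept,
                   significant = e$verdict$significant,
                   isometric = e$verdict$isometric)
      })
      skiprows <- lapply(names(g$sma$skipped), function(nm)
        data.frame(pair = nm, n = g$sma$skipped[[nm]]$n,
                   reason = g$sma$skipped[[nm]]$reason))
      if (length(smarows))
        utils::write.table(do.call(rbind, smarows),
                           file.path(config$out_dir, paste0("sma_", slug, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
      if (length(skiprows))
        utils::write.table(do.call(rbind, skiprows),
                           file.path(config$out_dir, paste0("sma_skipped_", slug, ".tsv")),
                           sep = "\t", row.names = FALSE, quote = FALSE, na = "NA")
    }
    if (!is.null(g$report)) {
      grid <- report_grid(g$report)
      utils::write.table(cbind(criterion = rownames(grid), grid),
                         file.path(config$out_dir, paste0("grid_", slug, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  writeLines(out$log, file.path(config$out_dir, "run.log"))
  bundle <- serialize_results(out)
  jsonlite::write_json(bundle, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(config$out_dir)
}

serialize_results <- function(out) {
  strip <- function(x) {
    if (inherits(x, "phylo") || is.function(x)) return(NULL)
    if (is.list(x)) {
      x <- lapply(unclass(x), strip)
      x[!vapply(x, is.null, TRUE)]
    } else x
  }
  list(config = out$config_summary,
       groups = lapply(out$groups, function(g)
         strip(g[c("group", "type1", "ols", "pgls", "type2", "sma")])),
       grids = lapply(out$groups, function(g)
         if (!is.null(g$report)) as.data.frame(report_grid(g$report)) else NULL),
       log = out$log)
}
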