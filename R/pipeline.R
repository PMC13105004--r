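#' Full per-clade analysis
#'
#' Runs the complete workflow for one clade: match tree and data, scale
#' to unit depth, MCMC under the exponential analysis prior plus a
#' uniform-prior sensitivity run, maximum-likelihood fits of the full
#' and dysploidy-only models with AIC comparison, posterior predictive
#' adequacy, and conversion of the posterior dysploidy rate to
#' events/Myr. Stages are deterministic given `seed`.
#'
#' @param tree A `phylo` chronogram (branch lengths in Myr unless
#'   `depth_myr` is supplied).
#' @param karyotypes Karyotype table ([karyotype_table()]).
#' @param clade Clade name used in the report.
#' @param prior Analysis prior (default exponential, mean 1).
#' @param sensitivity_prior Prior for the sensitivity run, or `NULL` to
#'   skip it.
#' @param cfg An [mcmc_config()].
#' @param root A [root_policy()].
#' @param n_adequacy Posterior predictive replicates (0 skips the
#'   check).
#' @param n_starts Random starts for the ML fits.
#' @param depth_myr Root age override; defaults to the tree's own depth.
#' @param missing_policy Passed to [match_tree_data()].
#' @param out_dir If non-`NULL`, the report is written as JSON plus a
#'   CSV of posterior draws into this directory.
#' @return A list of class `clade_report`.
#' @export
run_clade <- function(tree, karyotypes, clade = "clade",
                      prior = prior_exponential(1),
                      sensitivity_prior = prior_uniform(0, 100),
                      cfg = mcmc_config(), root = root_policy("fitzjohn"),
                      n_adequacy = 200, n_starts = 5, depth_myr = NULL,
                      missing_policy = "drop", out_dir = NULL) {
  matched <- match_tree_data(tree, karyotypes, missing_policy = missing_policy)
  scaled <- scale_to_unit_depth(matched$tree)
  if (is.null(depth_myr)) depth_myr <- scaled$depth_myr
  utree <- scaled$tree
  kar <- matched$karyotypes
  space <- build_state_space(kar)

  post <- run_mcmc(utree, kar, model = model_spec("FULL"), prior = prior,
                   cfg = cfg, root = root, space = space)
  med <- apply(post$draws, 2, median)
  dys <- dysploidy_rate_per_myr(post, depth_myr)

  sens <- NULL
  if (!is.null(sensitivity_prior)) {
    cfg2 <- cfg; cfg2$seed <- cfg$seed + 1L
    s <- run_mcmc(utree, kar, model = model_spec("FULL"),
                  prior = sensitivity_prior, cfg = cfg2, root = root,
                  space = space)
    smed <- apply(s$draws, 2, median)
    sens <- list(posterior_median = smed,
                 dysploidy_rate_myr = dysploidy_rate_per_myr(s, depth_myr)$median,
                 max_rel_diff = max(abs(smed - med) / pmax(med, 1e-12)))
  }

  full <- fit_ml(utree, kar, model_spec("FULL"), n_starts = n_starts,
                 seed = cfg$seed, root = root, space = space)
  red <- fit_ml(utree, kar, model_spec("DYSPLOIDY_ONLY"), n_starts = n_starts,
                seed = cfg$seed, root = root, space = space)
  cmp <- compare_polyploidy_support(full, red)

  adequacy <- NULL
  if (n_adequacy > 0) {
    n_rep <- min(n_adequacy, nrow(post$draws))
    adequacy <- posterior_predictive_check(utree, kar, post, root = root,
                                           n_replicates = n_rep,
                                           seed = cfg$seed, space = space)
  }

  report <- structure(list(
    clade = clade,
    n_tips = ape::Ntip(utree),
    depth_myr = depth_myr,
    seed = cfg$seed,
    posterior_median = med,
    dysploidy_rate_myr = dys$median,
    dysploidy_rate_ci90 = unname(quantile(dys$rates, c(0.05, 0.95))),
    ess = post$ess,
    ess_pass = post$ess_pass,
    acceptance_rate = post$acceptance_rate,
    sensitivity = sens,
    ml = list(log_lik_full = full$log_lik, log_lik_reduced = red$log_lik,
              aic_full = full$aic, aic_reduced = red$aic,
              mle_full = unclass(full$mle)),
    delta_aic = cmp$delta_aic,
    polyploidy_support = cmp$strong_support,
    adequacy = if (!is.null(adequacy))
      list(ppp = adequacy$ppp, observed = adequacy$observed,
           n_replicates = adequacy$n_replicates),
    posterior = post), class = "clade_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report[setdiff(names(report), "posterior")],
                         file.path(out_dir, paste0(clade, "_report.json")),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write.csv(cbind(as.data.frame(post$draws),
                    log_posterior = post$log_posterior),
              file.path(out_dir, paste0(clade, "_draws.csv")),
              row.names = FALSE)
  }
  report
}

#' Per-clade analysis across a set of trees
#'
#' Repeats [run_clade()] over several trees for the same karyotype table
#' (e.g. a posterior tree set, to propagate phylogenetic uncertainty)
#' and pools the per-tree dysploidy-rate medians.
#'
#' @param trees A list of `phylo` objects.
#' @param ... Passed to [run_clade()].
#' @return A list with `reports` (one per tree) and `pooled` (median and
#'   range of the per-tree rate medians).
#' @export
run_clade_treeset <- function(trees, ...) {
  reports <- lapply(seq_along(trees), function(i)
    run_clade(trees[[i]], clade = paste0("tree_", i), ...))
  rates <- vapply(reports, `[[`, numeric(1), "dysploidy_rate_myr")
  list(reports = reports,
       pooled = list(rate_medians = rates, median = median(rates),
                     range = range(rates)))
}

#' Cross-clade analysis of a clade-rate table
#'
#' Computes the fold range, per-group geometric means, and for each
#' requested grouping level a one-way ANOVA, REML variance components
#' with ICC, and a permutation test of the F statistic; optionally PGLS
#' of log10 rate on each covariate over a backbone tree whose tips are
#' the clades.
#'
#' @param table Clade-rate table: columns `clade`, `rate_myr`, one or
#'   more label columns, optional covariate columns.
#' @param levels Label columns to decompose over (each needs >= 2
#'   distinct labels).
#' @param backbone Optional `phylo` over the clades, required for PGLS.
#' @param covariates Character vector of covariate column names for
#'   PGLS (`genome_size` is log10-transformed first).
#' @param n_perm Permutations for the significance test.
#' @param seed Integer seed.
#' @param out_dir If non-`NULL`, the report is written as JSON.
#' @return A list of class `global_report`.
#' @export
run_global <- function(table, levels = "group", backbone = NULL,
                       covariates = NULL, n_perm = 9999, seed = 1,
                       out_dir = NULL) {
  missing_lab <- setdiff(levels, names(table))
  if (length(missing_lab) > 0)
    stop("missing label column(s): ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  tab <- log_rates(table)
  decomp <- list()
  for (lev in levels) {
    labs <- tab[[lev]]
    if (length(unique(labs)) < 2) {
      decomp[[lev]] <- list(error = "insufficient groups: need >= 2 labels")
      next
    }
    an <- anova_oneway(tab$log10_rate, labs)
    vc <- reml_variance_components(tab$log10_rate, labs)
    pm <- permutation_test(tab$log10_rate, labs, statistic = "F",
                           n_perm = n_perm, seed = seed)
    decomp[[lev]] <- list(F = an$F, df = an$df, p_anova = an$p_anova,
                          sigma2_between = vc$sigma2_between,
                          sigma2_within = vc$sigma2_within,
                          icc = vc$icc, pct_between = vc$pct_between,
                          p_perm = pm$p_perm,
                          geometric_means = as.list(
                            geometric_mean_rates(tab, lev)))
  }
  pgls_res <- NULL
  if (!is.null(backbone) && length(covariates) > 0) {
    pgls_res <- lapply(setNames(covariates, covariates), function(cv) {
      x <- tab[[cv]]
      if (cv == "genome_size") x <- log10(x)
      names(x) <- tab$clade
      y <- setNames(tab$log10_rate, tab$clade)
      unclass(pgls(y, x, backbone))
    })
  }
  report <- structure(list(n_clades = nrow(tab),
                           fold_range = fold_range(tab),
                           decomposition = decomp,
                           pgls = pgls_res,
                           n_perm = n_perm, seed = seed),
                      class = "global_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "global_report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  report
}
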