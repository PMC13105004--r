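#' Summary statistics of a karyotype table
#'
#' The two adequacy statistics: sample variance of the haploid counts
#' (denominator N - 1) and Shannon entropy (natural log) of the
#' empirical frequencies of the distinct raw counts.
#'
#' @param karyotypes Karyotype table with >= 2 species with counts.
#' @return A list with `variance` and `entropy` (nats).
#' @export
tip_statistics <- function(karyotypes) {
  n <- karyotypes$haploid_n
  n <- n[!is.na(n)]
  if (length(n) < 2)
    stop("need >= 2 species with counts", call. = FALSE)
  p <- table(n) / length(n)
  list(variance = var(n), entropy = -sum(p * log(p)))
}

#' Posterior predictive adequacy check
#'
#' For each of `n_replicates` posterior draws (subsampled without
#' replacement), a root state is drawn from the root policy's
#' distribution under that draw, tip counts are simulated along the
#' tree by Gillespie simulation under that draw's rate matrix, and the
#' variance and entropy of the replicate counts are recorded. The
#' posterior predictive p-value for each statistic uses the add-one
#' estimator `ppp = (#{replicate >= observed} + 1) / (n_replicates + 1)`
#' (never exactly 0 or 1 beyond the add-one bounds); `ppp_two_sided`
#' reports `2 * min(ppp, 1 - ppp)`. Extreme p-values in either tail
#' indicate that the fitted model fails to reproduce that feature of
#' the data.
#'
#' @param tree Unit-depth `phylo` matched to `karyotypes`.
#' @param karyotypes Observed karyotype table.
#' @param sample A [run_mcmc()] posterior sample.
#' @param root A [root_policy()].
#' @param n_replicates Number of predictive replicates (must not exceed
#'   the number of retained draws).
#' @param seed Integer seed.
#' @param space State space; defaults to the observed-count space.
#' @return An object of class `adequacy_result`: `observed`,
#'   `predictive` (per-replicate statistic data frame), `ppp`,
#'   `ppp_two_sided`, `n_replicates`.
#' @export
posterior_predictive_check <- function(tree, karyotypes, sample,
                                       root = root_policy("fitzjohn"),
                                       n_replicates = 200, seed = 1,
                                       space = build_state_space(karyotypes)) {
  stopifnot(inherits(sample, "posterior_sample"))
  n_draws <- nrow(sample$draws)
  if (n_replicates > n_draws)
    stop("n_replicates (", n_replicates, ") exceeds the number of ",
         "posterior draws (", n_draws, ")", call. = FALSE)
  if (nrow(unique(sample$draws)) == 1)
    warning("degenerate posterior: all draws identical", call. = FALSE)
  obs <- tip_statistics(karyotypes)
  part <- tip_partials(karyotypes, space, tree)
  set.seed(seed)
  pick <- sample.int(n_draws, n_replicates)
  rep_seeds <- sample.int(2^30, n_replicates)
  vr <- en <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    par <- rate_params()
    par[colnames(sample$draws)] <- sample$draws[pick[r], ]
    Q <- build_rate_matrix(space, par)
    d <- root_state_distribution(tree, part, Q, root)
    set.seed(rep_seeds[r])
    root_state <- sample.int(space$size, 1, prob = d) + space$n_min - 1L
    sim <- simulate_counts(tree, space, par, root_state, seed = rep_seeds[r])
    st <- tip_statistics(sim$karyotypes)
    vr[r] <- st$variance; en[r] <- st$entropy
  }
  ppp <- c(variance = (sum(vr >= obs$variance) + 1) / (n_replicates + 1),
           entropy  = (sum(en >= obs$entropy) + 1) / (n_replicates + 1))
  structure(list(observed = obs,
                 predictive = data.frame(variance = vr, entropy = en),
                 ppp = ppp,
                 ppp_two_sided = 2 * pmin(ppp, 1 - ppp),
                 n_replicates = n_replicates),
            class = "adequacy_result")
}

#' @export
print.adequacy_result <- function(x, ...) {
  cat("Posterior predictive adequacy (", x$n_replicates, "replicates )\n")
  cat(sprintf("  variance: observed %.4f, ppp %.4f\n",
              x$observed$variance, x$ppp["variance"]))
  cat(sprintf("  entropy : observed %.4f, ppp %.4f\n",
              x$observed$entropy, x$ppp["entropy"]))
  invisible(x)
}
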