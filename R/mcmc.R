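#' Prior specifications for event rates
#'
#' The default analysis prior is exponential (weakly informative on a
#' unit-depth tree, where a rate of 1 means one expected event per
#' root-to-tip path); a uniform prior is provided for sensitivity
#' analysis.
#'
#' @param mean Mean of the exponential prior (> 0).
#' @return An object of class `prior_spec`.
#' @export
prior_exponential <- function(mean = 1) {
  stopifnot(mean > 0)
  structure(list(family = "exponential", mean = mean), class = "prior_spec")
}

#' @rdname prior_exponential
#' @param lo,hi Support of the uniform prior, `hi > lo >= 0`.
#' @export
prior_uniform <- function(lo = 0, hi = 100) {
  stopifnot(lo >= 0, hi > lo)
  structure(list(family = "uniform", lo = lo, hi = hi), class = "prior_spec")
}

#' Log prior density of a rate vector
#'
#' Sum of independent per-parameter log densities over the model's free
#' parameters; `-Inf` outside the uniform support.
#'
#' @param params A [rate_params()] vector.
#' @param prior A [prior_exponential()] or [prior_uniform()] spec,
#'   applied to every free parameter.
#' @param model A [model_spec()]; only free parameters contribute.
#' @export
log_prior <- function(params, prior, model = model_spec("FULL")) {
  stopifnot(inherits(prior, "prior_spec"))
  x <- unclass(as_rate_params(params))[model$free]
  if (prior$family == "exponential")
    sum(dexp(x, rate = 1 / prior$mean, log = TRUE))
  else {
    if (any(x < prior$lo | x > prior$hi)) return(-Inf)
    sum(dunif(x, prior$lo, prior$hi, log = TRUE))
  }
}

prior_start <- function(prior) {
  if (prior$family == "exponential") prior$mean else
    prior$lo + 0.1 * (prior$hi - prior$lo)
}

#' MCMC run configuration
#'
#' `n_steps` counts retained post-burn-in samples; an additional
#' `burn_in_frac` fraction of the total chain is run first and
#' discarded, so the total length is `ceiling(n_steps / (1 -
#' burn_in_frac))`. Proposals are multiplicative log-normal random walks
#' (one parameter at a time), with the per-parameter proposal scale
#' adapted toward 30--45% acceptance during burn-in only and frozen
#' afterwards.
#'
#' @param n_steps Retained draws (default 1000).
#' @param burn_in_frac Fraction of the total chain discarded as burn-in.
#' @param proposal_sd Initial log-scale proposal standard deviation.
#' @param seed Integer RNG seed.
#' @param ess_threshold Minimum acceptable per-parameter effective
#'   sample size; runs below it are flagged, not rejected.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_steps = 1000, burn_in_frac = 0.25,
                        proposal_sd = 0.3, seed = 1, ess_threshold = 200) {
  stopifnot(n_steps >= 1, burn_in_frac >= 0, burn_in_frac < 1,
            proposal_sd > 0, ess_threshold > 0)
  structure(list(n_steps = as.integer(n_steps), burn_in_frac = burn_in_frac,
                 proposal_sd = proposal_sd, seed = as.integer(seed),
                 ess_threshold = ess_threshold), class = "mcmc_config")
}

#' Sample the posterior of the event rates by Metropolis-Hastings
#'
#' One-at-a-time multiplicative log-normal random-walk proposals on each
#' free parameter, with the log-scale Jacobian included in the
#' acceptance ratio. The tree should be unit depth ([scale_to_unit_depth()])
#' and matched to the karyotype table ([match_tree_data()]). Identical
#' seeds give bit-identical draws.
#'
#' Passing `karyotypes = NULL` turns the likelihood off (constant
#' target), so the chain samples the prior — used to calibrate the
#' sampler.
#'
#' @param tree Unit-depth `phylo`.
#' @param karyotypes Aligned karyotype table, or `NULL` for
#'   prior-only sampling.
#' @param model A [model_spec()]; fixed parameters are held at 0.
#' @param prior A `prior_spec` applied to each free parameter.
#' @param cfg An [mcmc_config()].
#' @param root A [root_policy()].
#' @param space State space; defaults to [build_state_space()] on the
#'   observed counts (ignored when `karyotypes` is `NULL`).
#' @return An object of class `posterior_sample`: `draws` (matrix,
#'   retained draws x free parameters), `log_posterior`,
#'   `acceptance_rate`, `ess` (per parameter), `ess_pass`, `n_burn`,
#'   and the resolved configuration.
#' @export
run_mcmc <- function(tree, karyotypes, model = model_spec("FULL"),
                     prior = prior_exponential(1), cfg = mcmc_config(),
                     root = root_policy("fitzjohn"), space = NULL) {
  stopifnot(inherits(model, "model_spec"), inherits(cfg, "mcmc_config"))
  free <- model$free
  k <- sum(free)
  if (k == 0) stop("model has no free parameters", call. = FALSE)

  loglik_fun <- make_loglik_fun(tree, karyotypes, root, space)

  set.seed(cfg$seed)
  par <- rate_params()
  par[free] <- prior_start(prior)
  ll <- loglik_fun(par)
  lp <- log_prior(par, prior, model)
  if (!is.finite(ll + lp))
    stop("invalid starting point: non-finite posterior", call. = FALSE)

  total <- ceiling(cfg$n_steps / (1 - cfg$burn_in_frac))
  n_burn <- total - cfg$n_steps
  free_idx <- which(free)
  sds <- rep(cfg$proposal_sd, k)
  acc_win <- rej_win <- numeric(k)
  n_acc <- 0L; n_prop <- 0L
  stuck <- 0L
  draws <- matrix(NA_real_, cfg$n_steps, k,
                  dimnames = list(NULL, names(par)[free_idx]))
  lpost <- numeric(cfg$n_steps)

  for (step in seq_len(total)) {
    any_acc <- FALSE
    for (j in seq_len(k)) {
      i <- free_idx[j]
      prop <- par
      prop[i] <- par[i] * exp(rnorm(1, 0, sds[j]))
      lp_prop <- log_prior(prop, prior, model)
      if (is.finite(lp_prop)) {
        ll_prop <- loglik_fun(prop)
        # log Jacobian of the multiplicative proposal: log(theta') - log(theta)
        ratio <- (ll_prop + lp_prop) - (ll + lp) + log(prop[i]) - log(par[i])
      } else ratio <- -Inf
      n_prop <- n_prop + 1L
      if (is.finite(ratio) && log(runif(1)) < ratio) {
        par <- prop; ll <- ll_prop; lp <- lp_prop
        n_acc <- n_acc + 1L; acc_win[j] <- acc_win[j] + 1
        any_acc <- TRUE
      } else rej_win[j] <- rej_win[j] + 1
    }
    stuck <- if (any_acc) 0L else stuck + 1L
    if (stuck >= 200L)
      stop("stuck chain: 200 consecutive sweeps with no accepted proposal ",
           "(current rates: ", paste(signif(par, 4), collapse = ", "),
           "; proposal sds: ", paste(signif(sds, 3), collapse = ", "), ")",
           call. = FALSE)
    if (step <= n_burn && step %% 50 == 0) {
      rate <- acc_win / pmax(acc_win + rej_win, 1)
      sds[rate < 0.30] <- sds[rate < 0.30] * 0.8
      sds[rate > 0.45] <- sds[rate > 0.45] * 1.25
      acc_win[] <- 0; rej_win[] <- 0
    }
    if (step > n_burn) {
      r <- step - n_burn
      draws[r, ] <- par[free_idx]
      lpost[r] <- ll + lp
    }
  }

  ess <- apply(draws, 2, function(x) suppressWarnings(effective_sample_size(x)))
  structure(list(draws = draws, log_posterior = lpost,
                 acceptance_rate = n_acc / n_prop,
                 ess = ess, ess_pass = all(ess >= cfg$ess_threshold),
                 n_burn = n_burn, model = model, prior = prior, cfg = cfg,
                 proposal_sds = sds),
            class = "posterior_sample")
}

make_loglik_fun <- function(tree, karyotypes, root, space) {
  if (is.null(karyotypes)) return(function(params) 0)
  if (is.null(space)) space <- build_state_space(karyotypes)
  part <- tip_partials(karyotypes, space, tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  root_state <- if (root$mode == "fixed") as.integer(root$state) else 1L
  mode <- root_mode_code(root)
  function(params) {
    Q <- build_rate_matrix(space, params)
    cpp_prune_loglik(tr$edge, tr$edge.length, part, unname(Q), ntip,
                     ntip + tr$Nnode, mode, root_state)$loglik
  }
}

#' Effective sample size of an MCMC trace
#'
#' `ESS = N / (1 + 2 * sum(rho_k))`, with the autocorrelation sum
#' truncated by the initial-positive-sequence rule (consecutive lag
#' pairs are summed while their sum stays positive). The estimate is
#' clipped to `(0, N]`. A constant trace returns 1 with a warning.
#'
#' @param x Numeric trace of length >= 10.
#' @return Scalar ESS estimate.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10) stop("trace too short for ESS (need >= 10)", call. = FALSE)
  if (sd(x) == 0 || !is.finite(sd(x))) {
    warning("degenerate (constant) trace; ESS reported as 1", call. = FALSE)
    return(1)
  }
  K <- min(n - 1, 2000L)
  rho <- as.numeric(acf(x, lag.max = K, plot = FALSE)$acf)[-1]
  s <- 0
  k <- 1
  while (k <= length(rho)) {
    pair <- rho[k] + if (k + 1 <= length(rho)) rho[k + 1] else 0
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  max(min(n / (1 + 2 * s), n), 1e-12)
}

#' Dysploidy rate in events per million years
#'
#' The per-draw dysploidy rate is `(gain + loss) / depth_myr` (default;
#' set `combine = "mean"` for the average of the two rates), converting
#' rates fitted on a unit-depth tree to events/Myr via the clade's root
#' age.
#'
#' @param sample A [run_mcmc()] result (or a matrix of draws with `gain`
#'   and `loss` columns).
#' @param depth_myr Root-to-tip depth of the original tree, in Myr.
#' @param combine `"sum"` (gain + loss) or `"mean"`.
#' @return A list with `rates` (per-draw vector, events/Myr) and
#'   `median`.
#' @export
dysploidy_rate_per_myr <- function(sample, depth_myr,
                                   combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  stopifnot(depth_myr > 0)
  draws <- if (inherits(sample, "posterior_sample")) sample$draws else sample
  g <- if ("gain" %in% colnames(draws)) draws[, "gain"] else 0
  l <- if ("loss" %in% colnames(draws)) draws[, "loss"] else 0
  r <- (g + l) / depth_myr
  if (combine == "mean") r <- r / 2
  list(rates = r, median = median(r))
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat("Posterior sample:", nrow(x$draws), "retained draws (",
      x$n_burn, "burn-in ),", ncol(x$draws), "free parameters\n")
  cat("acceptance rate:", signif(x$acceptance_rate, 3), "\n")
  cat("posterior medians:\n")
  print(apply(x$draws, 2, median))
  cat("ESS:\n"); print(round(x$ess, 1))
  if (!x$ess_pass) cat("WARNING: ESS below threshold",
                       x$cfg$ess_threshold, "\n")
  invisible(x)
}
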