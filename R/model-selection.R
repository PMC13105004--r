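#' Model variants over the four event rates
#'
#' A model is defined by which of the four rates are free; fixed rates
#' are held at exactly 0. Presets: `"FULL"` (all four free),
#' `"DYSPLOIDY_ONLY"` (gain and loss free, both saltational rates —
#' polyploidy and demiploidy — fixed at 0), `"NO_POLY"` and `"NO_DEMI"`
#' (drop one saltational rate at a time, for a finer model ladder).
#'
#' @param preset One of `"FULL"`, `"DYSPLOIDY_ONLY"`, `"NO_POLY"`,
#'   `"NO_DEMI"`, or `"CUSTOM"` with `free` supplied.
#' @param free Logical vector of length 4 (gain, loss, poly, demi) for
#'   `"CUSTOM"`.
#' @return An object of class `model_spec` with fields `free` (named
#'   logical) and `k` (number of free parameters).
#' @export
model_spec <- function(preset = c("FULL", "DYSPLOIDY_ONLY", "NO_POLY",
                                  "NO_DEMI", "CUSTOM"),
                       free = NULL) {
  preset <- match.arg(preset)
  f <- switch(preset,
    FULL           = c(TRUE, TRUE, TRUE, TRUE),
    DYSPLOIDY_ONLY = c(TRUE, TRUE, FALSE, FALSE),
    NO_POLY        = c(TRUE, TRUE, FALSE, TRUE),
    NO_DEMI        = c(TRUE, TRUE, TRUE, FALSE),
    CUSTOM         = as.logical(free))
  if (length(f) != 4 || anyNA(f))
    stop("free must be a logical vector of length 4", call. = FALSE)
  names(f) <- c("gain", "loss", "poly", "demi")
  structure(list(preset = preset, free = f, k = sum(f)), class = "model_spec")
}

#' Maximum-likelihood fit of a rate model
#'
#' Bounded quasi-Newton (L-BFGS-B) optimization of the pruning
#' log-likelihood over log-transformed free rates, from `n_starts`
#' random starting points drawn from an exponential distribution with
#' mean `start_mean` (the analysis prior's scale). The best start is
#' kept; `converged` reports the optimizer status of that start.
#'
#' @inheritParams run_mcmc
#' @param n_starts Number of random starts (default 5).
#' @param seed Integer seed for the random starts.
#' @param start_mean Mean of the exponential start distribution.
#' @return An object of class `ctmc_fit`: `mle` (full [rate_params()]
#'   vector with fixed rates at 0), `log_lik`, `k`, `aic`, `n_starts`,
#'   `converged`, `model`.
#' @export
fit_ml <- function(tree, karyotypes, model = model_spec("FULL"),
                   n_starts = 5, seed = 1, root = root_policy("fitzjohn"),
                   space = NULL, start_mean = 1) {
  stopifnot(inherits(model, "model_spec"), n_starts >= 1)
  loglik_fun <- make_loglik_fun(tree, karyotypes, root, space)
  free_idx <- which(model$free)
  k <- model$k
  nll <- function(logx) {
    par <- rate_params()
    par[free_idx] <- exp(logx)
    ll <- loglik_fun(par)
    if (!is.finite(ll)) 1e10 else -ll
  }
  set.seed(seed)
  starts <- matrix(log(rexp(n_starts * k, rate = 1 / start_mean)),
                   n_starts, k)
  starts[1, ] <- log(rep(0.5, k))  # deterministic moderate start
  if (n_starts >= 2) {
    # near-boundary start: saltational rates tiny, so a model with free
    # poly/demi can always match its dysploidy-only reduction
    s2 <- c(gain = 0.5, loss = 0.5, poly = 1e-4, demi = 1e-4)[free_idx]
    starts[2, ] <- log(s2)
  }
  run_start <- function(par0) tryCatch(
    optim(par0, nll, method = "L-BFGS-B",
          lower = rep(-20, k), upper = rep(6, k),
          control = list(maxit = 500)),
    error = function(e) e)
  best <- NULL
  diags <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    fit <- run_start(starts[s, ])
    diags[[s]] <- fit
    if (inherits(fit, "error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("optimization failure: all ", n_starts, " starts failed (",
         paste(vapply(diags, function(d)
           if (inherits(d, "error")) conditionMessage(d) else "ok",
           character(1)), collapse = "; "), ")", call. = FALSE)
  polish <- run_start(best$par)  # restart from the winner
  if (!inherits(polish, "error") && polish$value < best$value) best <- polish
  mle <- rate_params()
  mle[free_idx] <- exp(best$par)
  ll <- -best$value
  structure(list(mle = mle, log_lik = ll, k = k, aic = 2 * k - 2 * ll,
                 n_starts = n_starts, converged = best$convergence == 0,
                 model = model),
            class = "ctmc_fit")
}

#' Akaike information criterion of a fit
#'
#' `AIC = 2k - 2 log L`. `aic_correct = TRUE` applies the small-sample
#' correction (AICc) with `n` observations.
#'
#' @param fit A [fit_ml()] result.
#' @param aic_correct Use AICc instead of AIC.
#' @param n Number of observations (tips), required for AICc.
#' @export
aic <- function(fit, aic_correct = FALSE, n = NULL) {
  stopifnot(is.finite(fit$log_lik))
  a <- 2 * fit$k - 2 * fit$log_lik
  if (aic_correct) {
    stopifnot(!is.null(n), n > fit$k + 1)
    a <- a + 2 * fit$k * (fit$k + 1) / (n - fit$k - 1)
  }
  a
}

#' AIC comparison of the full model against a nested reduction
#'
#' `delta_aic = AIC(reduced) - AIC(full)`; values above `threshold`
#' (default 5) are classified as strong support for the extra
#' (saltational) parameters of the full model. Ties favor the reduced
#' model (fewer parameters).
#'
#' @param full,reduced [fit_ml()] results; `reduced`'s free parameters
#'   must be a subset of `full`'s.
#' @param threshold Strong-support cutoff on delta AIC.
#' @return A list with `delta_aic`, `strong_support`, `best_model`
#'   (`"full"` or `"reduced"`).
#' @export
compare_polyploidy_support <- function(full, reduced, threshold = 5) {
  if (!all(reduced$model$free <= full$model$free) ||
      reduced$model$k >= full$model$k)
    stop("usage error: 'reduced' must be strictly nested in 'full'",
         call. = FALSE)
  d <- aic(reduced) - aic(full)
  list(delta_aic = d,
       strong_support = d > threshold,
       best_model = if (aic(full) < aic(reduced)) "full" else "reduced")
}

#' @export
print.ctmc_fit <- function(x, ...) {
  cat("ML fit (", x$model$preset, "): logL = ", sprintf("%.4f", x$log_lik),
      ", k = ", x$k, ", AIC = ", sprintf("%.4f", x$aic),
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(x$mle)
  invisible(x)
}
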