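#' Log-transform clade rates
#'
#' Adds a `log10_rate` column. Cross-clade summaries work on the log10
#' scale because rates are multiplicative quantities: the geometric mean
#' of a group is `10^(mean of its logs)`.
#'
#' @param table Clade-rate table with columns `clade` and `rate_myr`.
#' @return The table with a `log10_rate` column appended.
#' @export
log_rates <- function(table) {
  bad <- !is.finite(table$rate_myr) | table$rate_myr <= 0
  if (any(bad))
    stop("non-positive rate for clade(s): ",
         paste(table$clade[bad], collapse = ", "), call. = FALSE)
  table$log10_rate <- log10(table$rate_myr)
  table
}

#' Geometric mean rate per group
#'
#' @param table Clade-rate table.
#' @param group_col Name of the grouping column.
#' @return Named vector of per-group geometric mean rates.
#' @export
geometric_mean_rates <- function(table, group_col = "group") {
  table <- log_rates(table)
  m <- tapply(table$log10_rate, table[[group_col]], mean)
  setNames(10^as.vector(m), names(m))
}

#' Fold range of clade rates
#'
#' Ratio of the fastest to the slowest clade rate.
#'
#' @param table Clade-rate table, or a numeric vector of rates.
#' @export
fold_range <- function(table) {
  r <- if (is.data.frame(table)) table$rate_myr else table
  if (length(r) < 2) stop("need >= 2 clades", call. = FALSE)
  max(r) / min(r)
}

#' One-way ANOVA of values across groups
#'
#' `F = MS_between / MS_within` on `(G - 1, N - G)` degrees of freedom,
#' via [stats::lm()]. Zero within-group variance yields `F = Inf` with
#' a warning.
#'
#' @param values Numeric vector.
#' @param groups Group labels (coerced to factor).
#' @return A list with `F`, `df` (between, within), `p_anova`.
#' @export
anova_oneway <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (length(values) - nlevels(g) < 1)
    stop("no residual degrees of freedom", call. = FALSE)
  a <- suppressWarnings(anova(lm(values ~ g)))
  msw <- a$`Mean Sq`[2]
  msb <- a$`Mean Sq`[1]
  if (msw <= 1e-12 * max(msb, 1) || !is.finite(a$`F value`[1])) {
    warning("zero within-group variance; F reported as Inf", call. = FALSE)
    return(list(F = Inf, df = c(between = a$Df[1], within = a$Df[2]),
                p_anova = 0))
  }
  list(F = a$`F value`[1],
       df = c(between = a$Df[1], within = a$Df[2]),
       p_anova = a$`Pr(>F)`[1])
}

#' REML variance components of a one-way random-intercept model
#'
#' Fits `y_ij = mu + a_i + e_ij` with `a_i ~ N(0, sigma2_between)` and
#' `e_ij ~ N(0, sigma2_within)` by REML ([lme4::lmer()]); the
#' between-group component is constrained to be >= 0, so a boundary
#' estimate of exactly 0 (ICC = 0) is possible and meaningful.
#'
#' @inheritParams anova_oneway
#' @return A list with `sigma2_between`, `sigma2_within`, `icc`
#'   (`sigma2_between / (sigma2_between + sigma2_within)`), and
#'   `pct_between` (`100 * icc`).
#' @export
reml_variance_components <- function(values, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  d <- data.frame(y = values, g = g)
  m <- suppressMessages(lme4::lmer(
    y ~ 1 + (1 | g), data = d, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(m))
  s2b <- vc$vcov[vc$grp == "g"]
  s2w <- vc$vcov[vc$grp == "Residual"]
  icc <- s2b / (s2b + s2w)
  list(sigma2_between = s2b, sigma2_within = s2w, icc = icc,
       pct_between = 100 * icc)
}

#' Permutation test of a group-difference statistic
#'
#' Permutes group labels uniformly at random `n_perm` times and reports
#' the add-one p-value
#' `(#{stat_perm >= stat_obs} + 1) / (n_perm + 1)`. `statistic = "F"`
#' (one-way ANOVA F, computed vectorized over permutations) is the fast
#' path; `statistic = "icc"` refits the REML model per permutation and
#' is correspondingly slower.
#'
#' @inheritParams anova_oneway
#' @param statistic `"F"` or `"icc"`.
#' @param n_perm Number of permutations (>= 99; default 9999).
#' @param seed Integer seed.
#' @return A list with `p_perm`, `stat_obs`, `n_perm`.
#' @export
permutation_test <- function(values, groups, statistic = c("F", "icc"),
                             n_perm = 9999, seed = 1) {
  statistic <- match.arg(statistic)
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  g <- factor(groups)
  if (nlevels(g) < 2)
    stop("usage error: need >= 2 distinct group labels", call. = FALSE)
  set.seed(seed)
  if (statistic == "F") {
    n <- length(values)
    nj <- as.numeric(table(g))
    G <- nlevels(g)
    sst <- sum((values - mean(values))^2)
    corr <- sum(values)^2 / n
    fstat <- function(v) {
      sg <- rowsum(v, g)
      ssb <- sum(sg^2 / nj) - corr
      (ssb / (G - 1)) / ((sst - ssb) / (n - G))
    }
    stat_obs <- fstat(values)
    vm <- vapply(seq_len(n_perm), function(i) sample(values), numeric(n))
    sg <- rowsum(vm, g)                       # G x n_perm group sums
    ssb <- colSums(sg^2 / nj) - corr
    stat_perm <- (ssb / (G - 1)) / ((sst - ssb) / (n - G))
  } else {
    stat_obs <- reml_variance_components(values, g)$icc
    stat_perm <- vapply(seq_len(n_perm), function(i)
      reml_variance_components(sample(values), g)$icc, numeric(1))
  }
  list(p_perm = (sum(stat_perm >= stat_obs) + 1) / (n_perm + 1),
       stat_obs = stat_obs, n_perm = n_perm)
}

#' Phylogenetic generalized least squares
#'
#' Regression of `y` on `x` with Brownian-motion error covariance
#' `V_ij = shared root-to-MRCA path length` between tips `i` and `j`
#' (the Brownian rate cancels from the estimator). On a star phylogeny
#' `V` is proportional to the identity and PGLS reduces to OLS. The
#' slope is tested two-sided against a t distribution with `n - 2`
#' residual degrees of freedom.
#'
#' @param y,x Numeric vectors; if named, aligned to `tree$tip.label`,
#'   otherwise assumed to be in tip order.
#' @param tree A `phylo` whose tips are the observations (>= 3).
#' @return A list of class `pgls_result`: `slope`, `intercept`,
#'   `slope_se`, `t_slope`, `p_slope`, `n`.
#' @export
pgls <- function(y, x, tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- ape::Ntip(tree)
  if (n < 3) stop("need >= 3 tips", call. = FALSE)
  if (!is.null(names(y))) y <- y[tree$tip.label]
  if (!is.null(names(x))) x <- x[tree$tip.label]
  if (anyNA(y) || anyNA(x))
    stop("y and x must cover every tip of the tree", call. = FALSE)
  V <- ape::vcv(tree)
  Vi <- tryCatch(chol2inv(chol(V)), error = function(e)
    stop("singular phylogenetic covariance (duplicate zero-distance tips?)",
         call. = FALSE))
  X <- cbind(intercept = 1, slope = x)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  if (!is.finite(rcond(XtViX)) || rcond(XtViX) < 1e-12)
    stop("singular design: x has no variation", call. = FALSE)
  beta <- solve(XtViX, XtVi %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(crossprod(r, Vi %*% r)) / (n - 2)
  covb <- s2 * solve(XtViX)
  se <- sqrt(diag(covb))
  tval <- beta[2] / se[2]
  structure(list(slope = unname(beta[2]), intercept = unname(beta[1]),
                 slope_se = unname(se[2]), t_slope = unname(tval),
                 p_slope = unname(2 * pt(-abs(tval), df = n - 2)), n = n),
            class = "pgls_result")
}

#' @export
print.pgls_result <- function(x, ...) {
  cat(sprintf("PGLS (n = %d): slope = %.4f (se %.4f), p = %.4g\n",
              x$n, x$slope, x$slope_se, x$p_slope))
  invisible(x)
}
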