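#' Root treatment for the pruning likelihood
#'
#' The likelihood of discrete tip data must be summed over root states
#' under some weighting. `"fitzjohn"` (the default) weights each root
#' state by its own conditional likelihood, `w_i = L_i / sum_j L_j`;
#' `"uniform"` averages over states; `"fixed"` conditions on a single
#' known root state.
#'
#' @param mode `"fitzjohn"`, `"uniform"` or `"fixed"`.
#' @param state Haploid count of the fixed root state (required for
#'   `"fixed"`).
#' @return An object of class `root_policy`.
#' @export
root_policy <- function(mode = c("fitzjohn", "uniform", "fixed"), state = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed" && (is.null(state) || state < 1))
    stop("fixed root policy requires a positive root state", call. = FALSE)
  structure(list(mode = mode, state = state), class = "root_policy")
}

root_mode_code <- function(root) {
  switch(root$mode, fitzjohn = 0L, uniform = 1L, fixed = 2L)
}

#' Conditional tip likelihood vectors
#'
#' One column per tip (in `tree$tip.label` order): a one-hot vector at
#' the observed count, or all ones for tips whose count is `NA`
#' (ambiguous — such a tip carries no information).
#'
#' @param karyotypes Karyotype table aligned to the tree (one row per
#'   tip; see [match_tree_data()]).
#' @param space A [build_state_space()] object.
#' @param tree A `phylo` object.
#' @return A `size x n_tips` numeric matrix.
#' @export
tip_partials <- function(karyotypes, space, tree) {
  stopifnot(inherits(space, "state_space"), inherits(tree, "phylo"))
  idx <- match(tree$tip.label, karyotypes$species)
  if (anyNA(idx))
    stop("tips missing from karyotype table: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  counts <- karyotypes$haploid_n[idx]
  out <- matrix(0, space$size, length(counts),
                dimnames = list(space$states, tree$tip.label))
  for (j in seq_along(counts)) {
    n <- counts[j]
    if (is.na(n)) {
      out[, j] <- 1
    } else {
      if (n < space$n_min || n > space$n_max)
        stop("state-space error: count ", n, " for species '",
             tree$tip.label[j], "' lies outside [", space$n_min, ", ",
             space$n_max, "]", call. = FALSE)
      out[state_index(space, n), j] <- 1
    }
  }
  out
}

#' Pruning log-likelihood of karyotypes on a tree
#'
#' Post-order (Felsenstein pruning) likelihood of the tip data under the
#' CTMC with generator `Q`, with per-node rescaling of partials to guard
#' against underflow (scalers accumulated in log space). Transition
#' probabilities along branches are computed from an eigendecomposition
#' of `Q` when it is well conditioned, otherwise by scaling-and-squaring
#' per distinct branch length; polytomies are handled natively as a
#' product over children.
#'
#' @param tree A `phylo` object (typically unit depth).
#' @param partials Tip partials from [tip_partials()].
#' @param Q Generator from [build_rate_matrix()].
#' @param root A [root_policy()].
#' @return The log-likelihood (scalar; `-Inf` with attribute
#'   `impossible = TRUE` if the data have probability 0, e.g. under a
#'   fixed root state that cannot reach the data).
#' @export
log_likelihood <- function(tree, partials, Q, root = root_policy("fitzjohn")) {
  stopifnot(inherits(tree, "phylo"), inherits(root, "root_policy"))
  pr <- prune_internal(tree, partials, Q, root)
  structure(pr$loglik, impossible = isTRUE(pr$impossible))
}

prune_internal <- function(tree, partials, Q, root) {
  S <- nrow(Q)
  if (ncol(partials) != ape::Ntip(tree))
    stop("partials must have one column per tip", call. = FALSE)
  root_state <- 1L
  if (root$mode == "fixed") {
    if (root$state > S)
      stop("fixed root state ", root$state, " outside state space", call. = FALSE)
    root_state <- as.integer(root$state)
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  cpp_prune_loglik(tr$edge, tr$edge.length, partials, unname(Q),
                   ape::Ntip(tr), ape::Ntip(tr) + tr$Nnode,
                   root_mode_code(root), root_state)
}

#' Log-likelihood directly from data and rates
#'
#' Convenience wrapper: builds the state space (unless given), the rate
#' matrix and the tip partials, then calls [log_likelihood()].
#'
#' @inheritParams log_likelihood
#' @param karyotypes Karyotype table aligned to the tree.
#' @param params A [rate_params()] vector.
#' @param space Optional [build_state_space()] object.
#' @export
ctmc_loglik <- function(tree, karyotypes, params,
                        space = build_state_space(karyotypes),
                        root = root_policy("fitzjohn")) {
  Q <- build_rate_matrix(space, params)
  part <- tip_partials(karyotypes, space, tree)
  log_likelihood(tree, part, Q, root)
}

#' Root-state distribution implied by a root policy
#'
#' Probability vector over states from which replicate root states are
#' drawn in posterior predictive simulation: the normalized root
#' conditional likelihoods for `"fitzjohn"`, the uniform distribution
#' for `"uniform"`, or a point mass for `"fixed"`.
#'
#' @inheritParams log_likelihood
#' @return A probability vector of length `nrow(Q)`.
#' @keywords internal
root_state_distribution <- function(tree, partials, Q, root) {
  S <- nrow(Q)
  if (root$mode == "uniform") return(rep(1 / S, S))
  if (root$mode == "fixed") {
    p <- numeric(S); p[root$state] <- 1
    return(p)
  }
  pr <- prune_internal(tree, partials, Q, root)
  d <- as.numeric(pr$root_dist)
  if (sum(d) <= 0) rep(1 / S, S) else d / sum(d)
}
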