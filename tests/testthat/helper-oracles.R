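# Independent oracles used across the suite. These deliberately avoid
# the package's pruning/propagation code paths.

# Log-likelihood by exhaustive enumeration over internal-node states.
# Transition probabilities come from transition_matrix() (dense matrix
# exponential), the likelihood itself from brute-force summation.
enum_loglik <- function(tree, counts, Q, root_mode = "uniform",
                        root_state = NULL) {
  S <- nrow(Q)
  ntip <- ape::Ntip(tree)
  nn <- tree$Nnode
  Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
    suppressWarnings(transition_matrix(Q, tree$edge.length[e])))
  Lroot <- numeric(S)
  grids <- expand.grid(rep(list(seq_len(S)), nn))
  for (g in seq_len(nrow(grids))) {
    asg <- as.integer(grids[g, ])
    st <- function(node) if (node <= ntip) counts[node] else asg[node - ntip]
    pr <- 1
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * Ps[[e]][st(tree$edge[e, 1]), st(tree$edge[e, 2])]
    Lroot[asg[1]] <- Lroot[asg[1]] + pr   # root = first internal node
  }
  switch(root_mode,
         uniform  = log(mean(Lroot)),
         fixed    = log(Lroot[root_state]),
         fitzjohn = log(sum(Lroot^2) / sum(Lroot)))
}

# Truncated-series matrix exponential: sum_{k<=K} (Qt)^k / k!
series_expm <- function(Q, t, K = 40) {
  S <- nrow(Q)
  acc <- diag(S)
  term <- diag(S)
  for (k in seq_len(K)) {
    term <- term %*% (Q * t) / k
    acc <- acc + term
  }
  acc
}

# Small fixed trees
cherry <- function(len = 1) read_tree(sprintf("(A:%g,B:%g);", len, len))
three_tip <- function() read_tree("((A:0.2,B:0.2):0.3,C:0.5);")

random_rates <- function() {
  rate_params(gain = runif(1, 0, 2), loss = runif(1, 0, 2),
              poly = runif(1, 0, 1), demi = runif(1, 0, 1))
}
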