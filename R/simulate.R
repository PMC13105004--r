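#' Simulate a unit-depth Yule tree
#'
#' Pure-birth tree grown to a fixed number of tips ([ape::rphylo()] with
#' zero extinction), then rescaled to unit depth; ultrametric by
#' construction.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @param birth Speciation rate (affects only relative node heights).
#' @return A unit-depth `phylo` with `depth_myr` attribute 1.
#' @export
simulate_yule_tree <- function(n_tips, seed = 1, birth = 1) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = 0)
  scale_to_unit_depth(tree)$tree
}

# Deterministic per-branch RNG streams keyed by the set of tip labels
# descending from the branch, so simulations are invariant to tip
# ordering and edge numbering.
branch_seed <- function(seed, labels) {
  key <- paste(sort(labels), collapse = ";")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 2147483563
  as.integer((h + as.numeric(seed) * 48271) %% 2147483563) + 1L
}

#' Simulate chromosome counts along a tree (Gillespie)
#'
#' Evolves a haploid count from `root_state` down the tree under the
#' four-rate process with exact (event-time) stochastic simulation: on
#' each branch, waiting times are exponential with the current state's
#' total rate `-Q[s, s]` and event targets are drawn proportional to the
#' off-diagonal rates of `Q`, so boundary truncation matches
#' [build_rate_matrix()] exactly. Each branch uses its own RNG stream
#' keyed by the tip labels it subtends, so results do not depend on tip
#' order.
#'
#' @param tree A `phylo` object (any depth).
#' @param space A [build_state_space()] object.
#' @param params A [rate_params()] vector.
#' @param root_state Haploid count at the root (must lie in `space`).
#' @param seed Integer seed.
#' @return A list with `karyotypes` (table of tip counts) and `events`
#'   (data frame: `branch` = child node id, `time` from the branch
#'   start, `from`, `to`, `type`).
#' @export
simulate_counts <- function(tree, space, params, root_state, seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(space, "state_space"))
  params <- as_rate_params(params)
  if (root_state < space$n_min || root_state > space$n_max)
    stop("root_state outside state space", call. = FALSE)
  trans <- transition_table(space, params)
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- ape::Ntip(tr)
  n_nodes <- ntip + tr$Nnode
  state <- integer(n_nodes)
  state[ntip + 1L] <- as.integer(root_state)
  desc <- descendant_tips(tr)
  ev <- list()
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    labs <- tr$tip.label[desc[[ch]]]
    set.seed(branch_seed(seed, labs))
    sim <- gillespie_branch(state[p], tr$edge.length[e], trans)
    state[ch] <- sim$state
    if (nrow(sim$events) > 0) {
      sim$events$branch <- ch
      ev[[length(ev) + 1L]] <- sim$events
    }
  }
  events <- if (length(ev) > 0) do.call(rbind, ev)
            else data.frame(time = numeric(0), from = integer(0),
                            to = integer(0), type = character(0),
                            branch = integer(0))
  list(karyotypes = karyotype_table(tr$tip.label, state[seq_len(ntip)]),
       events = events[, c("branch", "time", "from", "to", "type")])
}

descendant_tips <- function(tree) {
  ntip <- ape::Ntip(tree)
  n_nodes <- ntip + tree$Nnode
  desc <- vector("list", n_nodes)
  for (i in seq_len(ntip)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge)))
    desc[[po$edge[e, 1]]] <- c(desc[[po$edge[e, 1]]], desc[[po$edge[e, 2]]])
  desc
}

# Per-state event menu (target, rate, type), mirroring build_rate_matrix
# including mass-preserving truncation at n_max.
transition_table <- function(space, params) {
  nmx <- space$n_max
  lapply(space$states, function(n) {
    tg <- integer(0); rt <- numeric(0); ty <- character(0)
    put <- function(target, rate, type) {
      if (rate > 0) {
        tg <<- c(tg, min(target, nmx)); rt <<- c(rt, rate); ty <<- c(ty, type)
      }
    }
    if (n + 1 <= nmx) put(n + 1, params[["gain"]], "gain")
    if (n - 1 >= space$n_min) put(n - 1, params[["loss"]], "loss")
    put(2 * n, params[["poly"]], "poly")
    if (n %% 2 == 0) put(1.5 * n, params[["demi"]], "demi")
    else {
      put(floor(1.5 * n), params[["demi"]] / 2, "demi")
      put(ceiling(1.5 * n), params[["demi"]] / 2, "demi")
    }
    keep <- tg != n  # truncation onto the current state is a non-event
    list(target = tg[keep], rate = rt[keep], type = ty[keep],
         total = sum(rt[keep]))
  })
}

gillespie_branch <- function(state, len, trans) {
  t <- 0
  ev_t <- numeric(0); ev_from <- integer(0); ev_to <- integer(0)
  ev_ty <- character(0)
  repeat {
    menu <- trans[[state]]
    if (menu$total <= 0) break
    t <- t + rexp(1, menu$total)
    if (t > len) break
    j <- if (length(menu$rate) == 1) 1L
         else sample.int(length(menu$rate), 1, prob = menu$rate)
    ev_t <- c(ev_t, t); ev_from <- c(ev_from, state)
    ev_to <- c(ev_to, menu$target[j]); ev_ty <- c(ev_ty, menu$type[j])
    state <- menu$target[j]
  }
  list(state = state,
       events = data.frame(time = ev_t, from = ev_from, to = ev_to,
                           type = ev_ty, stringsAsFactors = FALSE))
}

#' Synthetic clade-rate table with two-level structure
#'
#' Generates per-clade dysploidy rates (events/Myr) with a known
#' group-level variance share: group means on the log10 scale are drawn
#' `N(grand_mean_log10, sd_between^2)` and clade log10 rates
#' `N(group mean, sd_within^2)`, so the true intraclass correlation is
#' `sd_between^2 / (sd_between^2 + sd_within^2)`.
#'
#' Defaults emulate the cross-clade conditions this package targets: a
#' grand geometric mean near 0.023 events/Myr and a within-group spread
#' (`sd_within = 0.6` log10 units) that yields roughly three orders of
#' magnitude between the slowest and fastest of ~55 clades.
#'
#' @param n_groups Number of groups (>= 2).
#' @param n_per_group Clades per group; scalar or vector of length
#'   `n_groups` (unbalanced designs allowed).
#' @param grand_mean_log10 Grand mean of log10 rate.
#' @param sd_between,sd_within Between-group and within-group standard
#'   deviations of log10 rate.
#' @param seed Integer seed.
#' @return A `data.frame(clade, rate_myr, group)` with attribute
#'   `true_icc`.
#' @export
make_clade_rate_table <- function(n_groups, n_per_group,
                                  grand_mean_log10 = log10(0.023),
                                  sd_between = 0, sd_within = 0.6,
                                  seed = 1) {
  stopifnot(n_groups >= 2, sd_between >= 0, sd_within > 0)
  sizes <- rep_len(n_per_group, n_groups)
  set.seed(seed)
  gmeans <- rnorm(n_groups, grand_mean_log10, sd_between)
  logs <- unlist(lapply(seq_len(n_groups),
                        function(g) rnorm(sizes[g], gmeans[g], sd_within)))
  group <- rep(paste0("group_", seq_len(n_groups)), sizes)
  out <- data.frame(clade = paste0("clade_", seq_along(logs)),
                    rate_myr = 10^logs, group = group,
                    stringsAsFactors = FALSE)
  attr(out, "true_icc") <- sd_between^2 / (sd_between^2 + sd_within^2)
  out
}

#' Simulate Brownian-motion tip values on a tree
#'
#' Root value 0; each branch adds an independent
#' `N(0, sigma^2 * branch_length)` increment. Used to generate
#' covariates with known phylogenetic covariance for PGLS tests.
#'
#' @param tree A `phylo` object.
#' @param sigma Diffusion standard deviation per unit sqrt(time) (>= 0).
#' @param seed Integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_brownian <- function(tree, sigma, seed = 1) {
  stopifnot(inherits(tree, "phylo"), sigma >= 0)
  set.seed(seed)
  tr <- ape::reorder.phylo(tree, "cladewise")
  ntip <- ape::Ntip(tr)
  val <- numeric(ntip + tr$Nnode)
  inc <- rnorm(nrow(tr$edge), 0, sigma * sqrt(tr$edge.length))
  for (e in seq_len(nrow(tr$edge)))
    val[tr$edge[e, 2]] <- val[tr$edge[e, 1]] + inc[e]
  setNames(val[seq_len(ntip)], tr$tip.label)
}
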