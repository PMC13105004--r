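test_that("Yule simulator: unit depth, ultrametric, deterministic", {
  tr2 <- simulate_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(tr2), 2)
  expect_equal(unname(tr2$edge.length), c(1, 1))

  tr <- simulate_yule_tree(50, seed = 1)
  expect_true(validate_ultrametric(tr, 1e-9))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-12)

  expect_identical(ape::write.tree(simulate_yule_tree(100, seed = 1)),
                   ape::write.tree(simulate_yule_tree(100, seed = 1)))
  expect_false(identical(ape::write.tree(simulate_yule_tree(100, seed = 1)),
                         ape::write.tree(simulate_yule_tree(100, seed = 2))))
  expect_error(simulate_yule_tree(1), ">= 2")
})

test_that("zero rates propagate the root state with an empty event log", {
  tr <- simulate_yule_tree(25, seed = 3)
  sp <- build_state_space(20, padding_factor = 1)
  sim <- simulate_counts(tr, sp, rate_params(), root_state = 9, seed = 4)
  expect_true(all(sim$karyotypes$haploid_n == 9))
  expect_equal(nrow(sim$events), 0)
})

test_that("simulation is seed-deterministic and tip-order invariant", {
  tr <- simulate_yule_tree(30, seed = 5)
  sp <- build_state_space(40, padding_factor = 1)
  pars <- rate_params(gain = 0.8, loss = 0.5, poly = 0.2, demi = 0.1)
  s1 <- simulate_counts(tr, sp, pars, 10, seed = 6)
  s2 <- simulate_counts(tr, sp, pars, 10, seed = 6)
  expect_identical(s1$karyotypes, s2$karyotypes)
  s3 <- simulate_counts(tr, sp, pars, 10, seed = 7)
  expect_false(identical(s1$karyotypes, s3$karyotypes))

  # branch RNG streams are keyed by subtended tip labels, so a ladderized
  # copy of the tree gives the same per-species counts
  trl <- ape::ladderize(tr)
  s4 <- simulate_counts(trl, sp, pars, 10, seed = 6)
  m <- merge(s1$karyotypes, s4$karyotypes, by = "species")
  expect_equal(m$haploid_n.x, m$haploid_n.y)
})

test_that("with polyploidy dominant the first event is a doubling", {
  sp <- build_state_space(64, padding_factor = 1)
  tr <- cherry(1)
  sim <- simulate_counts(tr, sp, rate_params(poly = 5), root_state = 4,
                         seed = 8)
  ev <- sim$events
  expect_true(nrow(ev) > 0)
  first <- ev[order(ev$branch, ev$time), ]
  # with all other rates 0, every event doubles the current count
  expect_true(all(first$to == pmin(2 * first$from, 64)))
  expect_true(all(first$type == "poly"))
})

test_that("pure-gain counts over a unit branch are Poisson(rate)", {
  # star tree: many independent endpoint draws from one branch of length 1
  star <- ape::stree(2000, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  sp <- build_state_space(1000, padding_factor = 1)
  sim <- simulate_counts(star, sp, rate_params(gain = 2), root_state = 100,
                         seed = 9)
  jumps <- sim$karyotypes$haploid_n - 100
  expect_gt(mean(jumps), 1.85)
  expect_lt(mean(jumps), 2.15)
  expect_lt(abs(var(jumps) - 2) / 2, 0.2)  # Poisson variance = mean
})

test_that("replaying the event log reproduces every tip state", {
  tr <- simulate_yule_tree(40, seed = 10)
  sp <- build_state_space(40, padding_factor = 1)
  sim <- simulate_counts(tr, sp, rate_params(gain = 1, loss = 0.7, poly = 0.3),
                         root_state = 10, seed = 11)
  ntip <- ape::Ntip(tr)
  state <- integer(ntip + tr$Nnode)
  state[ntip + 1L] <- 10L
  tro <- ape::reorder.phylo(tr, "cladewise")
  for (e in seq_len(nrow(tro$edge))) {
    p <- tro$edge[e, 1]; ch <- tro$edge[e, 2]
    s <- state[p]
    ev <- sim$events[sim$events$branch == ch, , drop = FALSE]
    if (nrow(ev) > 0) {
      ev <- ev[order(ev$time), ]
      expect_equal(ev$from[1], s)
      s <- ev$to[nrow(ev)]
    }
    state[ch] <- s
  }
  expect_equal(state[seq_len(ntip)], sim$karyotypes$haploid_n,
               ignore_attr = TRUE)
})

test_that("single-branch tip frequencies match the matrix exponential row", {
  star <- ape::stree(10000, type = "star")
  star$edge.length <- rep(0.5, nrow(star$edge))
  sp <- build_state_space(20, padding_factor = 2)
  pars <- rate_params(gain = 0.6, loss = 0.9, poly = 0.3, demi = 0.2)
  sim <- simulate_counts(star, sp, pars, root_state = 10, seed = 12)
  Q <- build_rate_matrix(sp, pars)
  expected <- transition_matrix(Q, 0.5)[10, ]
  emp <- tabulate(sim$karyotypes$haploid_n, nbins = sp$n_max) / 10000
  tv <- sum(abs(emp - expected)) / 2
  expect_lt(tv, 0.03)
})

test_that("clade-rate tables carry the designed group structure", {
  t0 <- make_clade_rate_table(3, 18, sd_between = 0, sd_within = 0.5, seed = 1)
  expect_equal(attr(t0, "true_icc"), 0)
  expect_equal(nrow(t0), 54)
  t5 <- make_clade_rate_table(4, 8, sd_between = 0.5, sd_within = 0.5, seed = 2)
  expect_equal(attr(t5, "true_icc"), 0.5)
  expect_true(all(t5$rate_myr > 0))

  # unbalanced sizes: ANOVA degrees of freedom (G-1, N-G)
  tu <- make_clade_rate_table(3, c(43, 11, 1), seed = 3)
  expect_equal(nrow(tu), 55)
  a <- anova_oneway(log10(tu$rate_myr), tu$group)
  expect_equal(unname(a$df), c(2, 52))
})

test_that("Brownian tip values have the tree's covariance structure", {
  tr <- cherry(1)
  expect_equal(unname(simulate_brownian(tr, sigma = 0, seed = 1)),
               c(0, 0))
  vals <- vapply(1:4000, function(s) simulate_brownian(tr, 1.5, seed = s),
                 numeric(2))
  expect_lt(abs(var(vals[1, ]) - 1.5^2) / 1.5^2, 0.1)
  expect_lt(abs(cor(vals[1, ], vals[2, ])), 0.05)

  star <- ape::stree(5, type = "star")
  star$edge.length <- rep(1, 5)
  sv <- vapply(1:3000, function(s) simulate_brownian(star, 1, seed = s),
               numeric(5))
  cors <- cor(t(sv))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.08)
})
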