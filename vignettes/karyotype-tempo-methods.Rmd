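---
title: "Models and methods behind karyotempo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind karyotempo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the model

How fast do chromosome numbers evolve? `karyotempo` treats the haploid
chromosome count of a species as a discrete character evolving along a
time-calibrated phylogeny under a continuous-time Markov chain with four
event types:

* **gain** — ascending dysploidy, $n \to n+1$ (fission);
* **loss** — descending dysploidy, $n \to n-1$ (fusion);
* **poly** — polyploidy, $n \to 2n$ (whole-genome duplication);
* **demi** — demiploidy, $n \to 1.5n$ (e.g. triploid-bridge outcomes).

All four rates are state-independent constants. The generator $Q$ on the
state space $\{1, \dots, n_{\max}\}$ places rate `gain` on $n \to n+1$,
`loss` on $n \to n-1$, `poly` on $n \to \min(2n, n_{\max})$, and `demi`
on $n \to 1.5n$; for odd $n$ the demiploidy rate is split half and half
between $\lfloor 1.5n \rfloor$ and $\lceil 1.5n \rceil$, the rounding
convention of the ChromEvol model family (the half that lands on $n$
itself at $n = 1$ is a non-event). Transitions that would overshoot
$n_{\max}$ are truncated *onto* $n_{\max}$ rather than dropped, so no
probability mass is lost at the boundary; rows of $Q$ sum to zero
exactly. The default state space spans 1 to twice the largest observed
count (`padding_factor = 2`), so one round of polyploidy from any
observed state stays in-space and truncation is rare where the data
live. The padding factor is exposed because the bound is an
approximation whose sensitivity should be checked per dataset, not
assumed.

## Likelihood

The likelihood of the observed tip counts is computed by Felsenstein's
pruning algorithm: a post-order pass in which each node's conditional
likelihood vector is the elementwise product over its children of
$P(t_{\text{child}})\,L_{\text{child}}$, with
$P(t) = e^{Qt}$. Three numerical choices matter:

* **Uniformization.** $e^{Qt}v$ along each branch is computed by
  uniformization: with $\lambda = \max_i(-Q_{ii})$ and
  $A = I + Q/\lambda$, $e^{Qt}v = \sum_k \mathrm{Pois}(k; \lambda t)
  A^k v$. Because $Q$ has at most five nonzero off-diagonals per row,
  each term is a sparse matrix–vector product, and every term is
  non-negative, so the scheme is stable for any rate values — including
  boundary cases (e.g. a pure-gain $Q$) where $Q$ is defective and an
  eigendecomposition route breaks down. Poisson weights are accumulated
  relative to their running maximum and renormalized, guarding against
  underflow at large $\lambda t$. The dense matrix exponential
  (`transition_matrix()`, scaling-and-squaring) is kept as an
  independent route and the two are cross-checked in the test suite,
  together with an exhaustive enumeration oracle on small trees.
* **Underflow scaling.** Partial likelihood vectors are rescaled to
  maximum 1 at every step with the log scalers accumulated, so
  likelihoods on trees of hundreds of tips stay finite.
* **Root treatment.** How to weight root states is a genuinely open
  modeling choice, so it is exposed as a policy: FitzJohn weighting
  ($w_i = L_i / \sum_j L_j$, the default), a uniform average, or a
  fixed state. Both FitzJohn and uniform treatments are runnable so
  sensitivity to the choice can be reported.

Tips without a count can be retained as fully ambiguous states
(all-ones partial vectors); polytomies are handled natively as products
over more than two children rather than resolved with zero-length
branches.

The plain CTMC likelihood is used throughout: there is no conditioning
on survival and no state-dependent diversification (SSE-class) term.
This is a documented modeling choice; rate estimates for traits that
strongly affect diversification would need an SSE treatment that is out
of scope here.

## Unit-depth trees and rate units

All inference happens on trees rescaled to unit root-to-tip depth. This
conditions the optimization and MCMC (rates are $O(1)$ numbers
regardless of clade age) and makes priors portable across clades. The
original depth in Myr is carried alongside and used only at reporting
time: a rate $r$ per unit tree depth on a clade of age $T$ Myr is
$r / T$ events/Myr. The conversion is exact division, tested to
machine precision. The reported **dysploidy rate** is gain + loss
(demiploidy and polyploidy excluded); the alternative convention, the
mean of gain and loss, is available via `combine = "mean"` in
`dysploidy_rate_per_myr()`.

## Bayesian estimation

`run_mcmc()` is a Metropolis–Hastings sampler with one-at-a-time
multiplicative log-normal random-walk proposals; the log-scale Jacobian
enters the acceptance ratio. Defaults:

* **Prior**: exponential with mean 1 per free rate — weakly informative
  at the unit-depth scale, where mean 1 means one expected event per
  root-to-tip path. The uniform sensitivity prior defaults to
  $(0, 100)$. Hyperparameters are declared choices, not estimates.
* **Chain length**: 1,000 retained draws after discarding an additional
  25% burn-in (total $\lceil 1000/0.75 \rceil$ sweeps). "Steps" always
  counts retained post-burn-in draws; both totals appear in the
  configuration echoed with every run.
* **Adaptation**: per-parameter proposal scales are tuned toward 30–45%
  acceptance during burn-in only and frozen afterwards, keeping the
  retained chain Markovian.
* **Diagnostics**: per-parameter effective sample size via
  $N / (1 + 2\sum_k \rho_k)$ with the initial-positive-sequence
  truncation rule; runs with any ESS below 200 are flagged
  (`ess_pass = FALSE`) but not discarded. A single chain is run by
  default.

Prior-only sampling (`karyotypes = NULL`) turns the likelihood off and
is used to verify that the sampler reproduces both prior families.

## Maximum likelihood and mode comparison

`fit_ml()` maximizes the same likelihood by L-BFGS-B on log-rates from
multiple starts: one moderate deterministic start (all rates 0.5), one
near-boundary start with tiny saltational rates — which guarantees the
full model can always match its dysploidy-only reduction — and the rest
drawn from the exponential prior; the winner is polished by a restart.
Support for polyploidy is classified by
$\Delta\mathrm{AIC} = \mathrm{AIC}_{\text{reduced}} -
\mathrm{AIC}_{\text{full}}$ with strong support above 5. The reduced
model drops *both* saltational rates (polyploidy and demiploidy
together), treating them as one "saltational" block against incremental
dysploidy; a finer ladder (`NO_POLY`, `NO_DEMI`) is provided for users
who want to separate them. AIC rather than AICc is the default, with
AICc behind a flag for small clades. Likelihood-ratio $\chi^2$ tests
are deliberately absent: rates fixed at 0 sit on the parameter
boundary, where the usual asymptotics fail.

## Model adequacy

`posterior_predictive_check()` simulates replicate tip datasets under
posterior draws (subsampled without replacement), drawing each
replicate's root state from the root policy's distribution *under that
draw* so root uncertainty propagates. Two statistics summarize each
dataset: the sample variance of the counts and the Shannon entropy (in
nats) of the empirical frequencies of the raw distinct counts — raw,
not binned, counts, since binning would add an arbitrary resolution
parameter. The posterior predictive p-value uses the add-one estimator
$(\#\{\text{rep} \ge \text{obs}\} + 1)/(n + 1)$, which can never
return 0; a doubled two-sided version is also reported because the
direction of model failure is not known in advance.

## The synthetic-data generator

`simulate_counts()` is an exact Gillespie simulator: exponential
waiting times at the current state's total exit rate, event types drawn
proportional to the off-diagonal rates of the *same* $Q$ used by the
likelihood, so simulator and likelihood agree about boundary truncation
by construction. Every branch consumes its own RNG stream keyed by the
set of tip labels it subtends, which makes simulations reproducible,
invariant to tip ordering, and stable under ladderization. The event
log (branch, time, from, to, type) is complete: replaying it
reproduces every tip state, which the test suite asserts.

`simulate_yule_tree()` draws pure-birth trees rescaled to unit depth.
`make_clade_rate_table()` draws per-clade log10 rates with a designed
between/within-group variance split (true ICC
$= \sigma_b^2 / (\sigma_b^2 + \sigma_w^2)$); its defaults — grand
geometric mean 0.023 events/Myr and within-group spread 0.6 log10 units
across ~55 clades — emulate the scale and dispersion of cross-clade
dysploidy-rate compilations, where rates span roughly three orders of
magnitude. `simulate_brownian()` provides covariates with known
phylogenetic covariance.

What the generator does *not* emulate: sampling bias in which species
get karyotyped, intraspecific count variation, tree estimation error,
and any dependence of diversification on the karyotype. Passing tests
therefore validate the estimator under its own model assumptions; they
do not certify robustness to those real-data complications.

## Cross-clade comparison

The comparative layer works on log10 rates throughout, because rates
are multiplicative (a geometric mean of rates is the exponentiated mean
of logs). It provides:

* one-way ANOVA (`anova_oneway()`, via `lm`), with $F = \infty$ and a
  warning when within-group variance is exactly zero;
* REML variance components (`reml_variance_components()`, via
  `lme4::lmer`) for the one-way random-intercept model, with the
  between-group variance constrained non-negative so a boundary ICC of
  exactly 0 is a legitimate estimate;
* permutation tests (`permutation_test()`, default 9,999 label
  permutations, add-one p-value). The F statistic has a vectorized
  fast path; permuting under the ICC statistic refits REML per
  permutation and is provided for completeness. Nested levels
  (kingdom vs higher taxon) are handled by running each level
  separately rather than by a nested permutation scheme;
* PGLS (`pgls()`) with plain Brownian covariance
  $V_{ij} = $ shared root-to-MRCA path length — no Pagel's
  $\lambda$ — reducing exactly to OLS on a star phylogeny. Genome size
  is log10-transformed before regression by `run_global()`; the slope
  is tested two-sided on $n - 2$ df.

Per-clade posterior uncertainty is *not* propagated into the
cross-clade layer: decomposition operates on posterior point medians,
which is the simplest defensible choice and is stated here explicitly.

## Orchestration

`run_clade()` chains the per-clade stages (match, rescale, MCMC with
exponential prior, uniform-prior sensitivity rerun, ML full + reduced,
$\Delta$AIC, posterior predictive check, per-Myr conversion) and
`run_global()` the cross-clade stages; both write JSON/CSV reports when
given an output directory, and both are deterministic given a seed.
`run_clade_treeset()` repeats the per-clade analysis across a set of
input trees (e.g. a posterior tree sample) and pools the per-tree rate
medians, which is how phylogenetic uncertainty is propagated. Tree
rescaling metadata (`depth_myr`) is an explicit input that can be
overridden, since different calibration workflows define clade age
differently.

## Validation conditions and known limitations

The acceptance-style tests in `tests/testthat/test-acceptance.R` run the
pipeline at these reference sizes, chosen to make the statistical
checks sharp while keeping a full run in minutes: likelihood vs
enumeration on 50 instances of ≤5 tips × ≤6 states; simulator vs
matrix-exponential on 10,000 single-branch replicates × 5 parameter
sets (total variation < 0.03); 50 recovery replicates on 150-tip trees
(gain = loss = 0.4; 90% intervals must cover ≥ 38/50 times); prior
sensitivity on a 300-tip clade (medians within 25%); ΔAIC
classification on 30 + 30 datasets (≤20% false support without
polyploidy, ≥60% detection with poly = 0.5); posterior predictive
calibration on 25 runs; permutation type-I error on 500 null tables
(rejection in [0.03, 0.07] at α = 0.05); REML ICC recovery at true ICC
0, 0.3, 0.7 (mean within 0.07); PGLS slope recovery (mean within 0.1 of
0.871) and star-tree equivalence to OLS at 1e-10; and exact unit
conversion. ML calibration fits use 3 starts — the deterministic,
near-boundary, and one prior start — which the nestedness guarantee
makes sufficient for the ΔAIC decision at threshold 5.

Known limitations, restated compactly: state-independent rates only (no
linear-in-$n$ terms, no base-number dysploidy parameter, no binary-state
dependence); no ancestral-state reconstruction; no survival
conditioning; single-chain MCMC by default; cross-clade decomposition
on point medians; PGLS is single-covariate with fixed Brownian
structure.
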