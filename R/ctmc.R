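#' Four event rates of chromosome-number change
#'
#' Bundles the rates of the four event types: `gain` (n -> n + 1,
#' ascending dysploidy), `loss` (n -> n - 1, descending dysploidy),
#' `poly` (polyploidy, n -> 2n) and `demi` (demiploidy, n -> 1.5n).
#' Rates are state-independent constants, in events per unit tree depth
#' unless stated otherwise.
#'
#' @param gain,loss,poly,demi Non-negative finite rates.
#' @return A named numeric vector of class `rate_params`.
#' @export
rate_params <- function(gain = 0, loss = 0, poly = 0, demi = 0) {
  x <- c(gain = gain, loss = loss, poly = poly, demi = demi)
  if (any(!is.finite(x)) || any(x < 0))
    stop("all rates must be finite and >= 0", call. = FALSE)
  structure(x, class = "rate_params")
}

#' Discrete state space over haploid counts
#'
#' States run from `n_min = 1` (a haploid count cannot be 0) to
#' `n_max = ceiling(padding_factor * max observed count)`. The default
#' `padding_factor = 2` guarantees that one round of polyploidy from the
#' largest observed count stays inside the space; transitions that would
#' overshoot `n_max` are truncated to `n_max` (see
#' [build_rate_matrix()]).
#'
#' @param karyotypes A karyotype table or a numeric vector of counts.
#' @param padding_factor Multiplier on the maximum observed count.
#' @return A list of class `state_space` with `n_min`, `n_max`, `size`,
#'   and `states` (the count each index represents).
#' @export
build_state_space <- function(karyotypes, padding_factor = 2) {
  counts <- if (is.data.frame(karyotypes)) karyotypes$haploid_n else karyotypes
  counts <- counts[!is.na(counts)]
  if (length(counts) == 0)
    stop("no observed counts: cannot build state space", call. = FALSE)
  n_max <- max(ceiling(padding_factor * max(counts)), max(counts))
  structure(list(n_min = 1L, n_max = as.integer(n_max),
                 size = as.integer(n_max), states = seq_len(n_max)),
            class = "state_space")
}

state_index <- function(space, count) count - space$n_min + 1L

#' Build the CTMC rate matrix
#'
#' Constructs the generator `Q` of the four-rate Markov process on the
#' given state space. From state `n`: rate `gain` to `n + 1` (if in
#' space), rate `loss` to `n - 1` (if in space), rate `poly` to
#' `min(2n, n_max)`, and demiploidy to `1.5n` — for even `n` the full
#' `demi` rate goes to `min(1.5n, n_max)`; for odd `n` the rate is split
#' half/half between `floor(1.5n)` and `ceiling(1.5n)` (both truncated
#' to `n_max`), the rounding convention of the ChromEvol model family.
#' Rates to a common target accumulate; truncation at the boundary is
#' mass-preserving, so the total rate leaving any state is exactly
#' `gain + loss + poly + demi` minus boundary-blocked dysploidy terms.
#'
#' @param space A [build_state_space()] object.
#' @param params A [rate_params()] vector.
#' @return A dense `size x size` matrix with zero row sums; dimnames are
#'   the haploid counts.
#' @export
build_rate_matrix <- function(space, params) {
  stopifnot(inherits(space, "state_space"))
  params <- as_rate_params(params)
  S <- space$size
  Q <- matrix(0, S, S, dimnames = list(space$states, space$states))
  nmx <- space$n_max
  for (n in space$states) {
    i <- state_index(space, n)
    add <- function(target, rate) {
      j <- state_index(space, min(target, nmx))
      Q[i, j] <<- Q[i, j] + rate
    }
    if (n + 1 <= nmx) add(n + 1, params[["gain"]])
    if (n - 1 >= space$n_min) add(n - 1, params[["loss"]])
    if (params[["poly"]] > 0) add(2 * n, params[["poly"]])
    if (params[["demi"]] > 0) {
      if (n %% 2 == 0) add(1.5 * n, params[["demi"]])
      else {
        add(floor(1.5 * n), params[["demi"]] / 2)
        add(ceiling(1.5 * n), params[["demi"]] / 2)
      }
    }
    Q[i, i] <- 0
    Q[i, i] <- -sum(Q[i, ])
  }
  Q
}

as_rate_params <- function(x) {
  if (inherits(x, "rate_params")) return(x)
  if (is.numeric(x) && length(x) == 4) {
    if (is.null(names(x))) names(x) <- c("gain", "loss", "poly", "demi")
    return(rate_params(x[["gain"]], x[["loss"]], x[["poly"]], x[["demi"]]))
  }
  stop("cannot interpret as rate_params", call. = FALSE)
}

#' Finite-time transition probabilities
#'
#' `P(t) = exp(Qt)` by scaling-and-squaring. Entries are clipped to
#' `[0, 1]` after exponentiation; a clip larger than 1e-9 triggers a
#' warning, and rows are checked to sum to 1 within 1e-9.
#'
#' @param Q A generator from [build_rate_matrix()].
#' @param t Non-negative elapsed time (same units as `Q`).
#' @return A stochastic matrix of the same dimension as `Q`.
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q), t >= 0)
  P <- cpp_expm(Q, t)
  if (any(!is.finite(P)))
    stop("numerical error: non-finite transition probabilities at t = ", t,
         call. = FALSE)
  dev <- max(0, max(-P), max(P - 1))
  if (dev > 1e-9)
    warning("transition probabilities clipped to [0,1]; max deviation ",
            signif(dev, 3), call. = FALSE)
  P[P < 0] <- 0
  P[P > 1] <- 1
  rs <- rowSums(P)
  if (max(abs(rs - 1)) > 1e-9)
    warning("transition matrix row sums deviate from 1 by up to ",
            signif(max(abs(rs - 1)), 3), call. = FALSE)
  dimnames(P) <- dimnames(Q)
  P
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Chromosome-change rates (per unit tree depth):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space over haploid counts ", x$n_min, "..", x$n_max,
      " (", x$size, " states)\n", sep = "")
  invisible(x)
}
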