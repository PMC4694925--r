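#' One deterministic network update
#'
#' Advances the binary states by one discrete time step:
#' `x(t+1) = Theta(W^EE x(t) - W^EI y(t) + W^EU u(t) - T^E(t))` followed by
#' `y(t+1) = Theta(W^IE x(t+1) - T^I)`, where `Theta` maps strictly positive
#' activations to 1 (an activation of exactly zero does not spike).  Inputs
#' drive only excitatory units.  This is the pure-R reference implementation
#' of the update used by the compiled phase runner in [runPhase()]; both are
#' cross-checked in the test suite.
#'
#' @param state a [SornState-class].
#' @param input either a single letter of the state's alphabet, `"_"` (or
#'   `NULL`) for a blank step, or an integer vector of excitatory unit
#'   indices to drive with weight `wIn` (an ambiguous cue).
#' @param noise optional numeric vector of per-unit perturbations added to
#'   the excitatory pre-threshold activation.
#' @return the updated [SornState-class].
#' @examples
#' st <- initNetwork(sornParams(nExc = 50L, seed = 2L))
#' st2 <- sornStep(st)
#' @export
sornStep <- function(state, input = NULL, noise = NULL) {
  stopifnot(all(state@x %in% c(0L, 1L)), all(state@y %in% c(0L, 1L)))
  drive <- numeric(nExc(state))
  if (!is.null(input) && !identical(input, "_")) {
    if (is.character(input)) {
      if (!input %in% state@alphabet)
        stop("unknown input letter: ", input)
      drive <- state@wEU[, input]
    } else {
      drive[as.integer(input)] <- drive[as.integer(input)] + state@params@wIn
    }
  }
  a <- drop(state@wEE %*% state@x) - drop(state@wEI %*% state@y) +
    drive - state@tE
  if (!is.null(noise)) a <- a + noise
  xNew <- as.integer(a > 0)
  yNew <- as.integer(drop(state@wIE %*% xNew) - state@tI > 0)
  state@x <- xNew
  state@y <- yNew
  state
}

#' Spike-timing dependent plasticity update
#'
#' Strengthens `W_ij` by `etaStdp` whenever a spike in unit `i` at `t+1`
#' directly follows a spike in unit `j` at `t`, and weakens it by `etaStdp`
#' for the reversed order.  Only existing synapses are modified; updated
#' weights are clipped at zero, and (when `pruneZeroWeights` is set) synapses
#' whose weight reaches zero are removed from the synapse mask.  Autapses are
#' never created.
#'
#' @param state a [SornState-class].
#' @param xPrev binary excitatory state at time `t`.
#' @param xNow binary excitatory state at time `t + 1`.
#' @return the updated [SornState-class].
#' @export
applyStdp <- function(state, xPrev, xNow) {
  stopifnot(length(xPrev) == nExc(state), length(xNow) == nExc(state),
            all(xPrev %in% 0:1), all(xNow %in% 0:1))
  eta <- state@params@etaStdp
  delta <- eta * (outer(xNow, xPrev) - outer(xPrev, xNow))
  delta[!state@synapses] <- 0
  w <- state@wEE + delta
  w[w < 0] <- 0
  if (state@params@pruneZeroWeights) {
    dropped <- state@synapses & delta < 0 & w == 0
    state@synapses[dropped] <- FALSE
  }
  state@wEE <- w
  state
}

#' Synaptic normalization sweep
#'
#' Applies one iteration of the combined pre- and postsynaptic normalization:
#' every weight is replaced by
#' `0.9 * W_ij + 0.1 * W_ij / (0.5 * sum_k W_ik + 0.5 * sum_k W_kj)`, which
#' pulls all incoming and outgoing excitatory weight sums towards 1 while
#' conserving the axonal arbor.  A doubly-normalized matrix (all nonzero row
#' and column sums equal to 1) is a fixed point.  Entries whose denominator
#' is zero (necessarily zero weights) are left unchanged.
#'
#' @param state a [SornState-class], or a bare non-negative weight matrix.
#' @return the updated state (or matrix).
#' @export
applySynapticNormalization <- function(state) {
  w <- if (is(state, "SornState")) state@wEE else state
  if (any(w < 0)) stop("negative weight in synaptic normalization")
  rs <- rowSums(w)
  cs <- colSums(w)
  d <- 0.5 * outer(rs, rep(1, ncol(w))) + 0.5 * outer(rep(1, nrow(w)), cs)
  d[d == 0] <- 1
  w <- 0.9 * w + 0.1 * w / d
  if (is(state, "SornState")) {
    state@wEE <- w
    state
  } else {
    w
  }
}

#' Intrinsic plasticity update
#'
#' Moves each excitatory threshold towards the regime where the neuron fires
#' at its individual target rate: `T^E <- T^E + etaIp * (x - H)`.  Thresholds
#' are unbounded; transient negative excursions self-correct because a
#' below-zero threshold makes the neuron fire, which raises the threshold
#' again.
#'
#' @param state a [SornState-class].
#' @param xNow binary excitatory state of the current step.
#' @return the updated [SornState-class].
#' @export
applyIp <- function(state, xNow) {
  stopifnot(length(xNow) == nExc(state), all(xNow %in% 0:1))
  state@tE <- state@tE + state@params@etaIp * (xNow - state@hTargets)
  state
}
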