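#' Construct SORN parameters
#'
#' Default values give the standard configuration: 200 excitatory and 40
#' inhibitory units, 10% directed excitatory connectivity, input pools of 10
#' units driven with weight 0.5, STDP and intrinsic-plasticity learning rates
#' of 0.001, target rates of 0.1 +/- 0.01 spikes per step, and excitatory
#' thresholds initialized in (0, 0.5).  The inhibitory threshold ceiling
#' `tIMax` is 0.35 for continuously stimulated tasks and should be set to 1
#' for trial-structured tasks with strong onset transients, where it balances
#' the active excitatory and inhibitory fractions.
#'
#' @param nExc number of excitatory units.
#' @param nInh number of inhibitory units (defaults to `round(0.2 * nExc)`).
#' @param pEE directed E-to-E connection probability.
#' @param nInput excitatory targets per input letter.
#' @param wIn input drive per targeted unit.
#' @param etaStdp STDP learning rate.
#' @param etaIp intrinsic-plasticity learning rate.
#' @param hIp mean target rate.
#' @param epsIp half-width of the per-neuron target-rate jitter.
#' @param tEMax ceiling of the initial excitatory thresholds.
#' @param tIMax ceiling of the inhibitory thresholds.
#' @param pruneZeroWeights drop synapses whose weight reaches zero.
#' @param structuralRate probability per plastic step of creating one new
#'   random synapse (0 disables structural plasticity).
#' @param structuralInit initial weight of structurally grown synapses.
#' @param noiseSd standard deviation of optional Gaussian perturbations of
#'   the excitatory activations.
#' @param seed default master seed.
#' @return a validated [SornParams-class] object.
#' @examples
#' p <- sornParams()
#' nExc(p)
#' @export
sornParams <- function(nExc = 200L, nInh = as.integer(round(0.2 * nExc)),
                       pEE = 0.1, nInput = 10L, wIn = 0.5,
                       etaStdp = 0.001, etaIp = 0.001,
                       hIp = 0.1, epsIp = 0.01,
                       tEMax = 0.5, tIMax = 0.35,
                       pruneZeroWeights = TRUE,
                       structuralRate = 0.1, structuralInit = 0.001,
                       noiseSd = 0, seed = 1L) {
  new("SornParams",
      nExc = as.integer(nExc), nInh = as.integer(nInh), pEE = pEE,
      nInput = as.integer(nInput), wIn = wIn,
      etaStdp = etaStdp, etaIp = etaIp, hIp = hIp, epsIp = epsIp,
      tEMax = tEMax, tIMax = tIMax,
      pruneZeroWeights = isTRUE(pruneZeroWeights),
      structuralRate = structuralRate, structuralInit = structuralInit,
      noiseSd = noiseSd, seed = as.integer(seed))
}

#' Derive independent child seeds from a master seed
#'
#' All randomness in the package is routed through named child streams
#' (network topology, threshold assignment, stimulus order, cue-unit draws,
#' per-phase structural/noise/shuffle draws, analysis subsampling) so that,
#' e.g., the stimulus sequence is reproducible independently of the network
#' topology.
#'
#' @param seed master seed (integer).
#' @param streams character vector of stream names.
#' @return named integer vector of child seeds.
#' @export
childSeeds <- function(seed, streams) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(streams))
  names(s) <- streams
  s
}
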