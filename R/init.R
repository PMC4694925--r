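#' Initialize a SORN state
#'
#' Builds the network: a sparse directed excitatory recurrent matrix with
#' connection probability `pEE` (no autapses), entries drawn uniformly from
#' `[0, 1]` and then normalized by iterated synaptic normalization until all
#' nonzero row and column sums are within `snTol` of 1; dense inhibitory
#' pathway matrices drawn uniformly and row-scaled so that the summed
#' excitatory weight received by each inhibitory unit and the summed
#' inhibitory weight received by each excitatory unit are exactly 1;
#' excitatory and inhibitory thresholds evenly spaced across `(0, tEMax)` and
#' `(0, tIMax)` and assigned to neurons in randomly permuted order; per-neuron
#' intrinsic-plasticity targets drawn uniformly from
#' `(hIp - epsIp, hIp + epsIp)`; and the initial excitatory state sampled
#' independently with per-neuron probability equal to its initial threshold
#' (inhibitory units start silent).
#'
#' @param params a [SornParams-class].
#' @param inputMap optional [InputMap-class]; when supplied the input weight
#'   matrix `wEU` is built with entries `wIn` on each letter's pool.
#' @param seed seed for the topology/threshold/initial-state draws; defaults
#'   to the seed stored in `params`.
#' @param snTol convergence tolerance for the initial synaptic normalization.
#' @return a [SornState-class].
#' @examples
#' st <- initNetwork(sornParams(nExc = 50L, seed = 7L))
#' range(rowSums(weightMatrix(st, "EI")))
#' @export
initNetwork <- function(params, inputMap = NULL, seed = params@seed,
                        snTol = 1e-3) {
  validObject(params)
  nE <- params@nExc
  nI <- params@nInh
  seeds <- childSeeds(seed, c("topology", "thresholds", "state"))

  set.seed(seeds[["topology"]])
  mask <- matrix(stats::runif(nE * nE) < params@pEE, nE, nE)
  diag(mask) <- FALSE
  wEE <- matrix(0, nE, nE)
  wEE[mask] <- stats::runif(sum(mask))
  if (any(mask)) {
    norm <- .cppSnNormalize(wEE, snTol, 10000L)
    wEE <- norm$W
  }
  wEI <- matrix(stats::runif(nE * nI), nE, nI)
  wEI <- wEI / rowSums(wEI)
  wIE <- matrix(stats::runif(nI * nE), nI, nE)
  wIE <- wIE / rowSums(wIE)

  set.seed(seeds[["thresholds"]])
  # midpoints of an even partition of the open interval, randomly permuted
  tE <- (params@tEMax * (seq_len(nE) - 0.5) / nE)[sample.int(nE)]
  tI <- (params@tIMax * (seq_len(nI) - 0.5) / nI)[sample.int(nI)]
  hTargets <- stats::runif(nE, params@hIp - params@epsIp,
                           params@hIp + params@epsIp)

  set.seed(seeds[["state"]])
  x <- as.integer(stats::runif(nE) < tE)
  y <- integer(nI)

  if (is.null(inputMap)) {
    wEU <- matrix(0, nE, 0)
    alphabet <- character()
  } else {
    validObject(inputMap)
    if (length(inputMap@disjoint) * params@nInput > nE)
      stop("not enough excitatory units for the requested disjoint pools")
    alphabet <- inputMap@alphabet
    wEU <- matrix(0, nE, length(alphabet),
                  dimnames = list(NULL, alphabet))
    for (l in alphabet) wEU[inputMap@pools[[l]], l] <- params@wIn
  }

  new("SornState",
      x = x, y = y, tE = tE, tI = tI, hTargets = hTargets,
      wEE = wEE, synapses = mask, wEI = wEI, wIE = wIE,
      wEU = wEU, alphabet = alphabet, params = params)
}
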