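#' @import methods
NULL

#' Parameters of a self-organizing recurrent network
#'
#' Holds the structural and plasticity parameters of the SORN: a population of
#' `nExc` binary excitatory threshold units and `nInh = round(0.2 * nExc)`
#' inhibitory units, sparse directed excitatory recurrence with connection
#' probability `pEE`, per-letter input pools of `nInput` units driven with
#' weight `wIn`, and the three plasticity rules (STDP with learning rate
#' `etaStdp`, synaptic normalization, and intrinsic plasticity with learning
#' rate `etaIp` towards per-neuron target rates drawn from
#' `(hIp - epsIp, hIp + epsIp)`).
#'
#' @slot nExc number of excitatory units.
#' @slot nInh number of inhibitory units; invariant `nInh == round(0.2 * nExc)`.
#' @slot pEE directed excitatory-to-excitatory connection probability.
#' @slot nInput number of excitatory targets per input letter.
#' @slot wIn input weight applied to each driven unit.
#' @slot etaStdp STDP learning rate.
#' @slot etaIp intrinsic-plasticity learning rate.
#' @slot hIp mean target firing rate (spikes per step).
#' @slot epsIp half-width of the uniform jitter around `hIp`.
#' @slot tEMax upper end of the initial excitatory threshold range.
#' @slot tIMax upper end of the inhibitory threshold range (0.35 for
#'   continuous-stimulation tasks, 1 for the trial-structured inference task).
#' @slot pruneZeroWeights drop synapses whose weight STDP drives to zero.
#' @slot structuralRate probability per plastic step of growing one new random
#'   non-autapse synapse.
#' @slot structuralInit initial weight of structurally created synapses.
#' @slot noiseSd standard deviation of optional Gaussian perturbations of the
#'   excitatory pre-threshold activation (0 = fully deterministic).
#' @slot seed default master seed used by [initNetwork()] and
#'   [runExperiment()].
#'
#' @seealso [sornParams()], [initNetwork()]
#' @export
setClass("SornParams",
  representation(
    nExc = "integer", nInh = "integer", pEE = "numeric", nInput = "integer",
    wIn = "numeric", etaStdp = "numeric", etaIp = "numeric",
    hIp = "numeric", epsIp = "numeric", tEMax = "numeric", tIMax = "numeric",
    pruneZeroWeights = "logical", structuralRate = "numeric",
    structuralInit = "numeric", noiseSd = "numeric", seed = "integer"
  )
)

setValidity("SornParams", function(object) {
  msg <- character()
  inUnit <- function(v) all(v >= 0 & v <= 1)
  if (object@nExc < 1L) msg <- c(msg, "nExc must be positive")
  if (object@nInh != as.integer(round(0.2 * object@nExc)))
    msg <- c(msg, "nInh must equal round(0.2 * nExc)")
  if (!inUnit(object@pEE)) msg <- c(msg, "pEE must lie in [0, 1]")
  if (!inUnit(object@hIp)) msg <- c(msg, "hIp must lie in [0, 1]")
  if (!inUnit(object@structuralRate))
    msg <- c(msg, "structuralRate must lie in [0, 1]")
  if (object@hIp - object@epsIp <= 0)
    msg <- c(msg, "hIp - epsIp must be strictly positive")
  if (object@nInput > object@nExc) msg <- c(msg, "nInput cannot exceed nExc")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Full mutable state of a SORN
#'
#' Binary excitatory and inhibitory state vectors, excitatory thresholds and
#' their per-neuron intrinsic-plasticity targets, fixed inhibitory thresholds,
#' and the four weight matrices.  Excitatory-to-excitatory weights are stored
#' densely together with a logical synapse mask so that a synapse whose weight
#' has been clipped to zero remains distinguishable from an absent one.
#'
#' @slot x binary excitatory state vector (length `nExc`).
#' @slot y binary inhibitory state vector (length `nInh`).
#' @slot tE excitatory thresholds (adapted by intrinsic plasticity).
#' @slot tI fixed inhibitory thresholds.
#' @slot hTargets per-neuron intrinsic-plasticity target rates.
#' @slot wEE excitatory-to-excitatory weight matrix (`nExc x nExc`, zero
#'   diagonal).
#' @slot synapses logical mask of existing excitatory synapses.
#' @slot wEI inhibitory-to-excitatory weights (`nExc x nInh`, rows sum to 1).
#' @slot wIE excitatory-to-inhibitory weights (`nInh x nExc`, rows sum to 1).
#' @slot wEU input weight matrix (`nExc x` number of letters; entries 0 or
#'   `wIn`).
#' @slot alphabet letters corresponding to the columns of `wEU`.
#' @slot params the [SornParams-class] the state was built from.
#'
#' @seealso [initNetwork()], [runPhase()]
#' @export
setClass("SornState",
  representation(
    x = "integer", y = "integer",
    tE = "numeric", tI = "numeric", hTargets = "numeric",
    wEE = "matrix", synapses = "matrix",
    wEI = "matrix", wIE = "matrix",
    wEU = "matrix", alphabet = "character",
    params = "SornParams"
  )
)

setValidity("SornState", function(object) {
  msg <- character()
  if (!all(object@x %in% c(0L, 1L))) msg <- c(msg, "x must be binary")
  if (!all(object@y %in% c(0L, 1L))) msg <- c(msg, "y must be binary")
  if (any(diag(object@wEE) != 0)) msg <- c(msg, "wEE must have zero diagonal")
  if (any(object@wEE < 0)) msg <- c(msg, "wEE must be non-negative")
  if (any(object@wEE[!object@synapses] != 0))
    msg <- c(msg, "wEE must be zero outside the synapse mask")
  if (any(object@wEI < 0) || any(object@wIE < 0))
    msg <- c(msg, "inhibitory pathway weights must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Recording of a simulated phase
#'
#' A time-by-neuron binary spike raster annotated with the input letter that
#' produced each state: row `t` holds the excitatory state `x(t+1)` that
#' resulted from presenting `letters[t]` (with `"_"` denoting a blank step).
#'
#' @slot spikes binary matrix, steps by excitatory units.
#' @slot inhSpikes optional binary matrix of inhibitory spikes (may have zero
#'   rows).
#' @slot letters character vector of presented symbols, one per step.
#' @slot phase label of the phase that produced the recording.
#'
#' @seealso [runPhase()], [spikeRaster()]
#' @export
setClass("SpikeRecording",
  representation(
    spikes = "matrix", inhSpikes = "matrix",
    letters = "character", phase = "character"
  )
)

setValidity("SpikeRecording", function(object) {
  msg <- character()
  if (nrow(object@spikes) != length(object@letters))
    msg <- c(msg, "letters must annotate every recorded step")
  if (length(msg)) msg else TRUE
})

#' Mapping from input letters to excitatory target pools
#'
#' Each letter of the alphabet projects onto a pool of `nInput` excitatory
#' units, sampled uniformly without replacement; pools of different letters
#' may overlap unless the letters are listed in `disjoint`.
#'
#' @slot alphabet the letters.
#' @slot pools named list of integer index vectors, one pool per letter.
#' @slot nInput pool size.
#' @slot disjoint letters whose pools are guaranteed mutually non-overlapping.
#'
#' @seealso [buildInputMap()]
#' @export
setClass("InputMap",
  representation(
    alphabet = "character", pools = "list",
    nInput = "integer", disjoint = "character"
  )
)

setValidity("InputMap", function(object) {
  msg <- character()
  if (!identical(names(object@pools), object@alphabet))
    msg <- c(msg, "pools must be named by the alphabet")
  if (!all(lengths(object@pools) == object@nInput))
    msg <- c(msg, "every pool must have exactly nInput members")
  if (length(object@disjoint) > 1) {
    idx <- unlist(object@pools[object@disjoint])
    if (anyDuplicated(idx))
      msg <- c(msg, "pools of disjoint letters must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' Symbolic stimulation task
#'
#' Words presented in random i.i.d. alternation according to `priors`, each
#' followed by a run of blank steps whose length is drawn uniformly from
#' `blankInterval = c(lo, hi)` (a fixed count when `lo == hi`).
#'
#' @slot words character vector of letter strings.
#' @slot priors word presentation probabilities (sum to 1).
#' @slot blankInterval integer range of blank steps after each word.
#' @slot phaseLengths named lengths of the self-organization, training and
#'   testing phases (steps).
#'
#' @seealso [taskSpec()], [sampleStimulusStream()]
#' @export
setClass("TaskSpec",
  representation(
    words = "character", priors = "numeric",
    blankInterval = "integer", phaseLengths = "integer"
  )
)

setValidity("TaskSpec", function(object) {
  msg <- character()
  if (length(object@words) != length(object@priors))
    msg <- c(msg, "words and priors must have equal length")
  if (abs(sum(object@priors) - 1) > 1e-8) msg <- c(msg, "priors must sum to 1")
  if (length(object@blankInterval) != 2L ||
      object@blankInterval[1] > object@blankInterval[2])
    msg <- c(msg, "blankInterval must be an ordered pair lo <= hi")
  if (length(msg)) msg else TRUE
})

#' Least-squares linear readout
#'
#' Linear maps from an excitatory state vector (plus an appended constant bias
#' regressor) to one output per class, trained by least squares.
#'
#' @slot weights numeric matrix, `(nExc + 1)` rows by one column per class;
#'   the last row is the bias.
#' @slot classes class labels.
#'
#' @seealso [fitDecisionReadout()], [decide()]
#' @export
setClass("LinearReadout",
  representation(weights = "matrix", classes = "character")
)

setValidity("LinearReadout", function(object) {
  if (ncol(object@weights) != length(object@classes))
    "one weight column per class required" else TRUE
})

#' Trial-aligned spike tensor
#'
#' Spikes re-cut into trials aligned at stimulus onset: a binary array of
#' dimension trials x time x neurons, with the within-trial index of the onset
#' step, one condition label per trial, and the mask of units that receive
#' direct sensory input (excluded from Fano-factor analyses).
#'
#' @slot spikes binary array `[trials, time, neurons]`.
#' @slot onset within-trial time index of stimulus onset (1-based).
#' @slot condition character vector, one label per trial.
#' @slot inputMask logical vector marking units with direct input.
#'
#' @seealso [alignTrials()], [fanoCurve()]
#' @export
setClass("TrialTensor",
  representation(
    spikes = "array", onset = "integer",
    condition = "character", inputMask = "logical"
  )
)

setValidity("TrialTensor", function(object) {
  msg <- character()
  d <- dim(object@spikes)
  if (length(d) != 3L) msg <- c(msg, "spikes must be a 3-d array")
  else {
    if (length(object@condition) != d[1])
      msg <- c(msg, "one condition label per trial required")
    if (length(object@inputMask) != d[3])
      msg <- c(msg, "inputMask must have one entry per neuron")
    if (object@onset < 1L || object@onset > d[2])
      msg <- c(msg, "onset must index a within-trial time step")
  }
  if (length(msg)) msg else TRUE
})

#' Noisy-channel Naive Bayes parameters
#'
#' Each of the `nUnits` input units of the cue populations A and B is treated
#' as an independent binary channel: a stimulated unit registers with
#' probability `theta1`, an unstimulated unit stays silent with probability
#' `theta0`.  `priorA` is the presentation probability of cue A during
#' learning.
#'
#' @slot theta1 probability of correct transmission of a stimulus.
#' @slot theta0 probability of correct transmission of a non-stimulus.
#' @slot nUnits input pool size per cue.
#' @slot priorA prior probability of cue A.
#'
#' @seealso [channelParams()], [posteriorCurve()]
#' @export
setClass("ChannelParams",
  representation(
    theta1 = "numeric", theta0 = "numeric",
    nUnits = "integer", priorA = "numeric"
  )
)

setValidity("ChannelParams", function(object) {
  p <- c(object@theta1, object@theta0, object@priorA)
  if (any(p < 0 | p > 1)) "theta1, theta0 and priorA must lie in [0, 1]"
  else if (object@nUnits < 1L) "nUnits must be positive" else TRUE
})

#' Posterior decision curve of the noisy-channel model
#'
#' The exact posterior probability p(A | f_A) of cue A for each ambiguity
#' fraction on the grid, together with the neutral fraction at which the
#' posterior crosses 0.5.
#'
#' @slot fGrid ambiguity fractions (multiples of 1/nUnits).
#' @slot pA posterior probability of A at each grid point.
#' @slot neutralF interpolated fraction with p(A | f_A) = 0.5 (`NA` flagged by
#'   `neutralAtBoundary` when the curve never crosses 0.5).
#' @slot neutralAtBoundary whether the 0.5 crossing fell outside the grid.
#'
#' @seealso [posteriorCurve()]
#' @export
setClass("PosteriorCurve",
  representation(
    fGrid = "numeric", pA = "numeric",
    neutralF = "numeric", neutralAtBoundary = "logical"
  )
)

setValidity("PosteriorCurve", function(object) {
  if (length(object@fGrid) != length(object@pA))
    "pA must have one value per grid point"
  else if (any(object@pA < -1e-12 | object@pA > 1 + 1e-12))
    "pA must lie in [0, 1]" else TRUE
})
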