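#' Run a simulation phase
#'
#' Iterates the network update together with the selected plasticity rules
#' over a stimulus stream (or over blank input for a spontaneous phase).
#' Within each step the order of operations is: state update, then STDP
#' (including structural growth/pruning), then synaptic normalization, then
#' intrinsic plasticity.  At the end of the phase the excitatory state vector
#' is shuffled by a uniform random permutation across neurons (unless
#' `shuffleEnd = FALSE`).
#'
#' The standard phase configurations are `plasticity = c("stdp", "sn", "ip")`
#' for the self-organization phase and `plasticity = "ip"` for training and
#' testing phases, where intrinsic plasticity remains active to keep the
#' average activity stable.
#'
#' @param state a [SornState-class].
#' @param stream a stimulus stream from [sampleStimulusStream()], or `NULL`
#'   for a spontaneous (blank-input) phase of `length` steps.
#' @param length number of steps when `stream` is `NULL`.
#' @param plasticity character subset of `c("stdp", "sn", "ip")`.
#' @param shuffleEnd shuffle the excitatory state across neurons at phase end.
#' @param seed seed for the phase's own randomness (structural plasticity,
#'   noise, end-of-phase shuffle).
#' @param label phase label stored in the recording.
#' @param recordInh also record inhibitory spikes.
#' @param snapshotEvery record connection fraction and total weight every so
#'   many steps (0 = never).
#' @return a list with elements `state` (updated [SornState-class]),
#'   `recording` (a [SpikeRecording-class]; row `t` holds the state produced
#'   by the input of step `t`), `snapshots` (data frame with columns `step`,
#'   `connectionFraction`, `totalWeight`), `noiseFlips` and `totalSpikes`.
#' @examples
#' st <- initNetwork(sornParams(nExc = 50L, seed = 3L))
#' out <- runPhase(st, length = 100L, plasticity = "ip", seed = 1L)
#' dim(spikeRaster(out$recording))
#' @export
runPhase <- function(state, stream = NULL, length = NULL,
                     plasticity = c("stdp", "sn", "ip"),
                     shuffleEnd = TRUE, seed = 1L, label = "phase",
                     recordInh = FALSE, snapshotEvery = 0L) {
  if (length(plasticity)) {
    plasticity <- match.arg(plasticity, c("stdp", "sn", "ip"),
                            several.ok = TRUE)
  }
  if (is.null(stream)) {
    if (is.null(length)) stop("either a stream or a length is required")
    stream <- blankStream(length)
  }
  nSteps <- base::length(stream$letters)
  if (nSteps == 0L) {
    rec <- new("SpikeRecording",
               spikes = matrix(0L, 0L, nExc(state)),
               inhSpikes = matrix(0L, 0L, nInh(state)),
               letters = character(), phase = label)
    return(list(state = state, recording = rec,
                snapshots = data.frame(step = integer(),
                                       connectionFraction = numeric(),
                                       totalWeight = numeric()),
                noiseFlips = 0, totalSpikes = 0))
  }
  drive <- .streamDrive(state, stream)
  p <- state@params

  set.seed(as.integer(seed))
  res <- .cppRunPhase(
    state@wEE, matrix(as.integer(state@synapses), nrow(state@synapses)),
    state@wEI, state@wIE,
    state@tE, state@tI, state@hTargets,
    as.numeric(state@x), as.numeric(state@y),
    drive$ptr, drive$idx, p@wIn,
    "stdp" %in% plasticity, "sn" %in% plasticity, "ip" %in% plasticity,
    p@pruneZeroWeights,
    if ("stdp" %in% plasticity) p@structuralRate else 0,
    p@structuralInit,
    p@etaStdp, p@etaIp, p@noiseSd,
    isTRUE(shuffleEnd), isTRUE(recordInh), as.integer(snapshotEvery))

  state@wEE <- res$Wee
  state@synapses <- matrix(res$mask != 0L, nrow(res$mask))
  state@tE <- drop(res$Te)
  state@x <- as.integer(drop(res$x))
  state@y <- as.integer(drop(res$y))

  spikes <- matrix(as.integer(res$spikes), nrow(res$spikes))
  inh <- if (recordInh) {
    matrix(as.integer(res$inhSpikes), nrow(res$inhSpikes))
  } else {
    matrix(0L, 0L, nInh(state))
  }
  rec <- new("SpikeRecording", spikes = spikes, inhSpikes = inh,
             letters = stream$letters, phase = label)
  list(state = state, recording = rec,
       snapshots = data.frame(step = res$snapshotStep,
                              connectionFraction = res$snapshotConnFrac,
                              totalWeight = res$snapshotTotalWeight),
       noiseFlips = res$noiseFlips, totalSpikes = res$totalSpikes)
}

# Build the CSR drive representation (0-based) for the compiled runner.
.streamDrive <- function(state, stream) {
  letters <- stream$letters
  cues <- stream$cueUnits
  nSteps <- length(letters)
  idxList <- vector("list", nSteps)
  for (t in seq_len(nSteps)) {
    if (!is.null(cues) && !is.null(cues[[t]])) {
      idxList[[t]] <- as.integer(cues[[t]]) - 1L
    } else if (letters[t] != "_") {
      if (!letters[t] %in% state@alphabet)
        stop("stream letter not in the state's alphabet: ", letters[t])
      idxList[[t]] <- which(state@wEU[, letters[t]] > 0) - 1L
    } else {
      idxList[[t]] <- integer()
    }
  }
  lens <- lengths(idxList)
  list(ptr = as.integer(c(0L, cumsum(lens))),
       idx = as.integer(unlist(idxList, use.names = FALSE)))
}

#' Blank stimulus stream
#'
#' @param length number of blank steps.
#' @return a stream presenting no input, usable with [runPhase()].
#' @export
blankStream <- function(length) {
  structure(list(letters = rep("_", length), cueUnits = NULL,
                 trials = NULL), class = "StimulusStream")
}
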