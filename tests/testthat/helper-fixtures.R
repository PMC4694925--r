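# Shared fixtures.  Heavy simulations are cached in a session-level
# environment so that several test files can consume the same realizations.

if (!exists(".sornCache", inherits = TRUE)) {
  .sornCache <- new.env(parent = emptyenv())
}

cached <- function(name, expr) {
  if (!exists(name, envir = .sornCache)) {
    assign(name, force(expr), envir = .sornCache)
  }
  get(name, envir = .sornCache)
}

# A small network used by fast unit tests.
tinyParams <- function(...) {
  sornParams(nExc = 50L, nInput = 5L, seed = 11L, ...)
}

# Hand-built state for micro-oracles: explicit weights and thresholds on a
# minimal network (5 excitatory / 1 inhibitory unit).
microState <- function(wEE = matrix(0, 5, 5), tE = rep(0.4, 5),
                       wEU = matrix(0, 5, 0), alphabet = character(),
                       x = integer(5), wIn = 0.5) {
  p <- sornParams(nExc = 5L, nInput = 1L, wIn = wIn, seed = 1L)
  new("SornState",
      x = as.integer(x), y = 0L,
      tE = tE, tI = 0.5, hTargets = rep(0.1, 5),
      wEE = wEE, synapses = wEE > 0,
      wEI = matrix(1, 5, 1), wIE = matrix(1 / 5, 1, 5),
      wEU = wEU, alphabet = alphabet, params = p)
}

# Synthetic recording from a bare spike matrix.
asRecording <- function(spikes, letters = rep("_", nrow(spikes)),
                        phase = "synthetic") {
  new("SpikeRecording", spikes = spikes,
      inhSpikes = matrix(0L, 0L, ncol(spikes)),
      letters = letters, phase = phase)
}

# --- shared heavy simulations -----------------------------------------------

# Full-scale inference realizations for the decision-curve fit: the nine
# training priors x 5 realizations per plasticity condition, standard phase
# lengths.  Only per-run summaries are retained.
accPriors <- seq(0.1, 0.9, by = 0.1)

runInferenceSummary <- function(prior, real, plasticity,
                                wantFano = FALSE, wantPrediction = FALSE) {
  res <- runExperiment("inference", sornParams(),
                       seed = 50000L + 1000L * real + round(100 * prior),
                       priorA = prior, plasticity = plasticity)
  dc <- decisionCurve(res$decisions)
  dc$prior <- prior
  dc$real <- real
  out <- list(curve = dc)
  if (wantFano || wantPrediction) {
    inputMask <- directInputMask(res$inputMap, nExc(res$params))
    trials <- res$testTrials
    rec <- res$recordings$testing
    if (wantFano) {
      ua <- trials[trials$fA %in% c(0, 1), , drop = FALSE]
      tUA <- alignTrials(rec, ua, pre = 8L, post = 8L,
                         inputMask = inputMask,
                         condition = ifelse(ua$fA == 1, "A", "B"))
      out$fano <- fanoCurve(tUA, byCondition = TRUE)
      tAll <- alignTrials(rec, trials, pre = 8L, post = 8L,
                          inputMask = inputMask)
      out$fanoAll <- fanoCurve(tAll)
      mm <- meanMatchedFano(tAll, seed = real)
      out$meanMatched <- mm
      out$discardFraction <- attr(mm, "discardFraction")
    }
    if (wantPrediction) {
      full <- alignTrials(rec, trials, pre = 6L, post = 8L,
                          inputMask = inputMask)
      pe <- rbind(predictEvokedActivity(full, offsets = 0:8,
                                        shuffle = FALSE, seed = real),
                  predictEvokedActivity(full, offsets = 0:8,
                                        shuffle = TRUE, seed = real))
      aligned <- trials$onset - 6L >= 1L &
        trials$onset + 8L <= nrow(spikeRaster(rec))
      decVec <- res$decisions$decision[
        match(trials$onset[aligned], res$decisions$onset)]
      pd <- rbind(predictDecisions(full, decVec, offsets = -5:4,
                                   shuffle = FALSE, seed = real),
                  predictDecisions(full, decVec, offsets = -5:4,
                                   shuffle = TRUE, seed = real))
      out$evokedPrediction <- pe
      out$decisionPrediction <- pd
    }
  }
  rm(res)
  gc(verbose = FALSE)
  out
}

accDecisionCurves <- function(plasticity = c("stdp", "sn", "ip"),
                              tag = "full", nReal = 10L) {
  cached(paste0("curves_", tag), {
    out <- list()
    for (p in accPriors) {
      for (r in seq_len(nReal)) {
        s <- runInferenceSummary(p, r, plasticity)
        out[[length(out) + 1L]] <- s$curve
      }
    }
    do.call(rbind, out)
  })
}

# Ten realizations of the prior-0.1 inference condition with Fano-factor
# summaries; the first also carries the prediction-suite summaries.
accQuenching <- function() {
  cached("quenching", {
    lapply(1:10, function(r)
      runInferenceSummary(0.1, 100L + r, c("stdp", "sn", "ip"),
                          wantFano = TRUE, wantPrediction = r <= 2))
  })
}

# One realization of the basic-properties task (ten random letters) at
# standard scale, with its spontaneous phase.
accRandomLetters <- function() {
  cached("randomLetters", {
    runExperiment("random_letters", sornParams(), seed = 77L)
  })
}

# One realization of the two-word 67/33 task at standard scale.
accTwoWord <- function() {
  cached("twoWord", {
    runExperiment("sequence_priors", sornParams(), seed = 91L,
                  priorA = 2 / 3)
  })
}

# Natural versus reversed-control evoked activity for the KL comparison:
# self-organize on the two words at equal priors, then record evoked
# activity for the imprinted words and for the control words from the same
# state, plus matched-length spontaneous activity.
accKlPair <- function() {
  cached("klPair", {
    params <- sornParams()
    seeds <- childSeeds(123L, c("map", "net", "so", "nat", "ctrl", "spont",
                                "units"))
    map <- buildInputMap(LETTERS[1:8], params, seed = seeds[["map"]])
    state <- initNetwork(params, map, seed = seeds[["net"]])
    spec <- taskSpec(c("ABCD", "EFGH"), blankInterval = 0L)
    so <- runPhase(state, sampleStimulusStream(spec, 50000L,
                                               seed = seeds[["so"]]),
                   plasticity = c("stdp", "sn", "ip"), seed = seeds[["so"]],
                   label = "self-organization")
    len <- 30000L
    natural <- runPhase(so$state,
                        sampleStimulusStream(spec, len, seed = seeds[["nat"]],
                                             exact = TRUE),
                        plasticity = "ip", seed = seeds[["nat"]],
                        label = "natural")
    ctrlSpec <- taskSpec(c("EDCBA", "HGF"), blankInterval = 0L)
    control <- runPhase(so$state,
                        sampleStimulusStream(ctrlSpec, len,
                                             seed = seeds[["ctrl"]],
                                             exact = TRUE),
                        plasticity = "ip", seed = seeds[["ctrl"]],
                        label = "control")
    spont <- runPhase(natural$state, length = len, plasticity = "ip",
                      seed = seeds[["spont"]], label = "spontaneous")
    set.seed(seeds[["units"]])
    units <- sort(sample.int(nExc(state), 16L))
    list(natural = natural$recording, control = control$recording,
         spontaneous = spont$recording, units = units)
  })
}

# Sequence-recognition realizations at reduced scale (20 per condition).
accSequenceRecognition <- function(control = FALSE) {
  cached(paste0("seqrec_", if (control) "control" else "trained"), {
    lens <- c(plastic = 20000L, train = 10000L, test = 10000L)
    t(vapply(1:20, function(r) {
      res <- runExperiment("sequence_recognition", sornParams(),
                           seed = 3000L + r + control * 500L,
                           phaseLengths = lens, control = control)
      m <- res$magnitude
      rm(res)
      gc(verbose = FALSE)
      m
    }, numeric(4)))
  })
}
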