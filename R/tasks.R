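#' Construct a task specification
#'
#' @param words character vector of letter strings.
#' @param priors word presentation probabilities (default uniform).
#' @param blankInterval blank steps after each word: a single fixed count or
#'   a `c(lo, hi)` range sampled uniformly.
#' @param phaseLengths named integer vector with elements `plastic`, `train`,
#'   `test`; defaults to the standard 50000 / 20000 / 50000 steps.
#' @return a [TaskSpec-class].
#' @examples
#' taskSpec(c("ABCD", "EFGH"), priors = c(2, 1) / 3, blankInterval = 0L)
#' @export
taskSpec <- function(words, priors = rep(1 / length(words), length(words)),
                     blankInterval = 0L,
                     phaseLengths = c(plastic = 50000L, train = 20000L,
                                      test = 50000L)) {
  if (length(blankInterval) == 1L) blankInterval <- rep(blankInterval, 2L)
  stopifnot(all(c("plastic", "train", "test") %in% names(phaseLengths)))
  new("TaskSpec", words = words, priors = priors,
      blankInterval = as.integer(blankInterval),
      phaseLengths = as.integer(phaseLengths[c("plastic", "train", "test")]) |>
        stats::setNames(c("plastic", "train", "test")))
}

#' Build the letter-to-pool input mapping
#'
#' Samples, for every letter, a pool of `nInput` excitatory target units
#' uniformly without replacement.  Pools of different letters may overlap,
#' except between the letters listed in `disjointLetters`, whose pools are
#' drawn jointly without replacement (required for well-defined ambiguous
#' cues in the inference task).
#'
#' @param alphabet character vector of letters.
#' @param params a [SornParams-class] (supplies `nExc` and `nInput`).
#' @param disjointLetters letters whose pools must not overlap.
#' @param seed seed for the pool draws.
#' @return an [InputMap-class].
#' @examples
#' m <- buildInputMap(LETTERS[1:4], sornParams(seed = 5L), seed = 5L)
#' lengths(inputPools(m))
#' @export
buildInputMap <- function(alphabet, params, disjointLetters = character(),
                          seed = params@seed) {
  nE <- params@nExc
  k <- params@nInput
  if (length(disjointLetters) * k > nE)
    stop("not enough excitatory units for the requested disjoint pools")
  set.seed(as.integer(seed))
  pools <- vector("list", length(alphabet))
  names(pools) <- alphabet
  if (length(disjointLetters)) {
    joint <- sample.int(nE, length(disjointLetters) * k)
    for (i in seq_along(disjointLetters))
      pools[[disjointLetters[i]]] <- sort(joint[((i - 1) * k + 1):(i * k)])
  }
  for (l in setdiff(alphabet, disjointLetters))
    pools[[l]] <- sort(sample.int(nE, k))
  new("InputMap", alphabet = alphabet, pools = pools,
      nInput = as.integer(k), disjoint = as.character(disjointLetters))
}

#' Sample a symbolic stimulus stream
#'
#' Draws words i.i.d. according to the task priors, emits each word's letters
#' in order, and appends a run of blank `"_"` steps whose length is drawn
#' uniformly from the task's blank interval.  Generation stops at the first
#' word boundary at or beyond `length` steps, so the stream length can exceed
#' `length` by at most one word plus one blank run.
#'
#' @param spec a [TaskSpec-class].
#' @param length target number of steps.
#' @param seed seed for word order and blank lengths.
#' @param exact trim the stream to exactly `length` steps.
#' @return a `StimulusStream`: a list with `letters` (symbol per step),
#'   `cueUnits` (`NULL`; see [inferenceTestStream()]), and `trials` (data
#'   frame with one row per word instance: `word`, `onset`, `fA = NA`).
#' @examples
#' spec <- taskSpec(c("AB", "CD"), blankInterval = 2L)
#' s <- sampleStimulusStream(spec, 20L, seed = 1L)
#' table(s$trials$word)
#' @export
sampleStimulusStream <- function(spec, length, seed = 1L, exact = FALSE) {
  stopifnot(length > 0)
  set.seed(as.integer(seed))
  chunks <- list()
  words <- list()
  onsets <- list()
  pos <- 0L
  k <- 0L
  while (pos < length) {
    k <- k + 1L
    w <- spec@words[sample.int(base::length(spec@words), 1L,
                               prob = spec@priors)]
    nb <- if (spec@blankInterval[1] == spec@blankInterval[2]) {
      spec@blankInterval[1]
    } else {
      sample(spec@blankInterval[1]:spec@blankInterval[2], 1L)
    }
    ls <- strsplit(w, "")[[1]]
    words[[k]] <- w
    onsets[[k]] <- pos + 1L
    chunks[[k]] <- c(ls, rep("_", nb))
    pos <- pos + base::length(ls) + nb
  }
  letters <- unlist(chunks, use.names = FALSE)
  words <- unlist(words, use.names = FALSE)
  onsets <- unlist(onsets, use.names = FALSE)
  if (exact && base::length(letters) > length) {
    letters <- letters[seq_len(length)]
    keep <- onsets <= length
    words <- words[keep]
    onsets <- onsets[keep]
  }
  structure(list(letters = letters, cueUnits = NULL,
                 trials = data.frame(word = words, onset = onsets,
                                     fA = NA_real_)),
            class = "StimulusStream")
}

#' Sample an ambiguous cue
#'
#' Builds the active-unit set of a mixed A/B cue: `round(fA * nInput)` units
#' drawn from the pool of A and the remaining units from the pool of B, both
#' uniformly without replacement.  The draw is repeated independently for
#' every trial.
#'
#' @param inputMap an [InputMap-class] with disjoint pools for `letterA` and
#'   `letterB`.
#' @param fA ambiguity fraction, a multiple of `1 / nInput`.
#' @param letterA,letterB the two cue letters.
#' @return integer vector of `nInput` excitatory unit indices.
#' @export
sampleAmbiguousCue <- function(inputMap, fA, letterA = "A", letterB = "B") {
  k <- inputMap@nInput
  nA <- round(fA * k)
  if (abs(fA * k - nA) > 1e-8)
    stop("fA must be a multiple of 1/nInput")
  poolA <- inputMap@pools[[letterA]]
  poolB <- inputMap@pools[[letterB]]
  c(if (nA > 0) sample(poolA, nA) else integer(),
    if (nA < k) sample(poolB, k - nA) else integer())
}

#' Testing-phase stream of ambiguous inference trials
#'
#' Each trial presents one ambiguous cue step (a mix of the A and B pools
#' parameterized by the trial's ambiguity fraction), followed by the mask
#' letters of the trial word (e.g. `"XXX"`), followed by the fixed delay of
#' 10 blank steps plus 0 to 5 additional blank steps drawn uniformly.
#' Ambiguity fractions are cycled through `fGrid` in random order so that all
#' classes are represented nearly equally.
#'
#' @param inputMap an [InputMap-class] with disjoint A/B pools.
#' @param length target number of steps.
#' @param fGrid ambiguity fractions to present.
#' @param mask letters following the cue step.
#' @param seed seed for fraction order, cue draws and delays.
#' @param fixedDelay,extraDelay blank-interval structure after each trial.
#' @return a `StimulusStream` whose `trials` data frame has columns `word`
#'   (`"A/B"`), `onset`, `fA`, and `decisionStep` — the recording row
#'   holding the network state at the first blank after the mask.  Under the
#'   recording convention (row `t` holds the state produced by the input of
#'   step `t`) this is the row of the final mask letter: the state present
#'   when the blank is shown.
#' @export
inferenceTestStream <- function(inputMap, length,
                                fGrid = (0:10) / 10,
                                mask = "XXX", seed = 1L,
                                fixedDelay = 10L, extraDelay = 0:5) {
  set.seed(as.integer(seed))
  maskLetters <- strsplit(mask, "")[[1]]
  trialLen <- 1L + base::length(maskLetters)
  chunks <- list()
  cues <- list()
  fs <- list()
  onsets <- list()
  pos <- 0L
  k <- 0L
  fQueue <- numeric(0)
  while (pos < length) {
    k <- k + 1L
    if (!base::length(fQueue)) fQueue <- sample(fGrid)
    f <- fQueue[1]
    fQueue <- fQueue[-1]
    nb <- fixedDelay + sample(extraDelay, 1L)
    units <- sampleAmbiguousCue(inputMap, f)
    stepLetters <- c("A/B", maskLetters, rep("_", nb))
    cue <- vector("list", base::length(stepLetters))
    cue[[1]] <- units
    chunks[[k]] <- stepLetters
    cues[[k]] <- cue
    fs[[k]] <- f
    onsets[[k]] <- pos + 1L
    pos <- pos + base::length(stepLetters)
  }
  onsets <- unlist(onsets, use.names = FALSE)
  structure(list(letters = unlist(chunks, use.names = FALSE),
                 cueUnits = do.call(c, cues),
                 trials = data.frame(word = "A/B", onset = onsets,
                                     fA = unlist(fs, use.names = FALSE),
                                     decisionStep = onsets + trialLen - 1L)),
            class = "StimulusStream")
}

# decision step (first blank after the mask) for word-presentation trials
.decisionSteps <- function(trials, wordLength) trials$onset + wordLength

#' Run a full three-phase experiment preset
#'
#' Executes self-organization (STDP + synaptic normalization + intrinsic
#' plasticity), then training (IP only, STDP frozen), then testing, for one
#' of the four study paradigms, and returns the recordings together with the
#' preset's analysis bundle:
#'
#' * `"random_letters"`: ten randomly alternating single-letter stimuli; the
#'   testing phase is spontaneous (no input).  Used for basic spike and
#'   weight statistics.
#' * `"sequence_recognition"`: training on `"ABCD"` (or on all 24 letter
#'   permutations when `control = TRUE`) with a fixed blank interval of 10
#'   steps, a "sleep" phase of spontaneous activity, then separate tests on
#'   `"ABCD"`, `"DCBA"`, `"A_CD"` and `"E_CD"` each started from the same
#'   post-sleep state; reports the mean population rate over the four word
#'   steps ("sequence magnitude") per test word.
#' * `"sequence_priors"`: continuous random alternation of `"ABCD"` and
#'   `"EFGH"` (no blanks) at configurable priors; the training phase records
#'   evoked activity, the testing phase records spontaneous activity.
#' * `"inference"`: words `"AXXX"` / `"BXXX"` with disjoint A/B pools,
#'   blank intervals of 10 to 15 steps and inhibitory threshold ceiling 1;
#'   the testing phase presents ambiguous A/B cues over the full ambiguity
#'   grid, a linear readout is trained on the training phase and the decision
#'   trace over test trials is returned.
#'
#' @param preset one of `"random_letters"`, `"sequence_recognition"`,
#'   `"sequence_priors"`, `"inference"`.
#' @param params a [SornParams-class]; `tIMax` is overridden to 1 for the
#'   inference preset unless `params` already sets it.
#' @param seed master seed for this realization.
#' @param priorA prior of the first word (presets with two words).
#' @param phaseLengths named vector `c(plastic=, train=, test=)`.
#' @param control for `"sequence_recognition"`: train on all permutations.
#' @param plasticity plasticity rules active during self-organization
#'   (training and testing always run IP only).  Set to `"ip"` for the
#'   IP-only ablation of the inference task.
#' @param fGrid ambiguity fractions for the inference test phase.
#' @return a list (class `"ExperimentResult"`) whose elements depend on the
#'   preset; common elements are `state`, `inputMap`, `recordings` (named
#'   list of [SpikeRecording-class]), `snapshots`, `params`, `seed`.
#' @examples
#' \donttest{
#' res <- runExperiment("random_letters", sornParams(),
#'                      phaseLengths = c(plastic = 2000L, train = 1000L,
#'                                       test = 2000L), seed = 1L)
#' names(res$recordings)
#' }
#' @export
runExperiment <- function(preset = c("random_letters", "sequence_recognition",
                                     "sequence_priors", "inference"),
                          params = sornParams(), seed = params@seed,
                          priorA = 2 / 3,
                          phaseLengths = c(plastic = 50000L, train = 20000L,
                                           test = 50000L),
                          control = FALSE,
                          plasticity = c("stdp", "sn", "ip"),
                          fGrid = (0:10) / 10) {
  preset <- match.arg(preset)
  seeds <- childSeeds(seed, c("map", "net", "streamSo", "streamTrain",
                              "streamTest", "phaseSo", "phaseTrain",
                              "phaseTest", "readout"))
  switch(preset,
    random_letters = .runRandomLetters(params, seeds, phaseLengths),
    sequence_recognition = .runSequenceRecognition(params, seeds,
                                                   phaseLengths, control),
    sequence_priors = .runSequencePriors(params, seeds, phaseLengths,
                                         priorA),
    inference = .runInference(params, seeds, phaseLengths, priorA,
                              plasticity, fGrid))
}

.runRandomLetters <- function(params, seeds, phaseLengths) {
  alphabet <- LETTERS[1:10]
  map <- buildInputMap(alphabet, params, seed = seeds[["map"]])
  state <- initNetwork(params, map, seed = seeds[["net"]])
  spec <- taskSpec(alphabet, blankInterval = 0L, phaseLengths = phaseLengths)
  so <- runPhase(state,
                 sampleStimulusStream(spec, phaseLengths[["plastic"]],
                                      seed = seeds[["streamSo"]]),
                 plasticity = c("stdp", "sn", "ip"),
                 seed = seeds[["phaseSo"]], label = "self-organization",
                 snapshotEvery = 500L)
  tr <- runPhase(so$state,
                 sampleStimulusStream(spec, phaseLengths[["train"]],
                                      seed = seeds[["streamTrain"]]),
                 plasticity = "ip", seed = seeds[["phaseTrain"]],
                 label = "training")
  te <- runPhase(tr$state, length = phaseLengths[["test"]],
                 plasticity = "ip", seed = seeds[["phaseTest"]],
                 label = "spontaneous")
  structure(list(preset = "random_letters", state = te$state,
                 inputMap = map, params = params,
                 recordings = list(selfOrganization = so$recording,
                                   training = tr$recording,
                                   spontaneous = te$recording),
                 snapshots = so$snapshots),
            class = "ExperimentResult")
}

.runSequenceRecognition <- function(params, seeds, phaseLengths, control) {
  alphabet <- LETTERS[1:5]
  testWords <- c("ABCD", "DCBA", "A_CD", "E_CD")
  trainWords <- if (control) {
    perms <- .permutations(c("A", "B", "C", "D"))
    vapply(perms, paste, "", collapse = "")
  } else "ABCD"
  map <- buildInputMap(alphabet, params, seed = seeds[["map"]])
  state <- initNetwork(params, map, seed = seeds[["net"]])
  spec <- taskSpec(trainWords, blankInterval = 10L,
                   phaseLengths = phaseLengths)
  so <- runPhase(state,
                 sampleStimulusStream(spec, phaseLengths[["plastic"]],
                                      seed = seeds[["streamSo"]]),
                 plasticity = c("stdp", "sn", "ip"),
                 seed = seeds[["phaseSo"]], label = "self-organization",
                 snapshotEvery = 500L)
  # "sleep": spontaneous period with IP only, defaulting to the training
  # phase length
  sleep <- runPhase(so$state, length = phaseLengths[["train"]],
                    plasticity = "ip", seed = seeds[["phaseTrain"]],
                    label = "sleep")
  testSeeds <- childSeeds(seeds[["phaseTest"]],
                          paste0("test_", testWords))
  streamSeeds <- childSeeds(seeds[["streamTest"]],
                            paste0("stream_", testWords))
  recs <- list(selfOrganization = so$recording, sleep = sleep$recording)
  magnitude <- stats::setNames(numeric(length(testWords)), testWords)
  drivenUnits <- sort(unique(unlist(inputPools(map), use.names = FALSE)))
  for (w in testWords) {
    wspec <- taskSpec(w, blankInterval = 10L, phaseLengths = phaseLengths)
    ws <- sampleStimulusStream(wspec, phaseLengths[["test"]],
                               seed = streamSeeds[[paste0("stream_", w)]])
    out <- runPhase(sleep$state, ws, plasticity = "ip",
                    seed = testSeeds[[paste0("test_", w)]],
                    label = paste0("test_", w))
    recs[[paste0("test_", w)]] <- out$recording
    magnitude[w] <- sequenceMagnitude(out$recording, ws$trials,
                                      nchar(w), units = drivenUnits)
  }
  structure(list(preset = "sequence_recognition", state = sleep$state,
                 inputMap = map, params = params, control = control,
                 recordings = recs, magnitude = magnitude,
                 snapshots = so$snapshots),
            class = "ExperimentResult")
}

.runSequencePriors <- function(params, seeds, phaseLengths, priorA) {
  alphabet <- LETTERS[1:8]
  map <- buildInputMap(alphabet, params, seed = seeds[["map"]])
  state <- initNetwork(params, map, seed = seeds[["net"]])
  spec <- taskSpec(c("ABCD", "EFGH"), priors = c(priorA, 1 - priorA),
                   blankInterval = 0L, phaseLengths = phaseLengths)
  so <- runPhase(state,
                 sampleStimulusStream(spec, phaseLengths[["plastic"]],
                                      seed = seeds[["streamSo"]]),
                 plasticity = c("stdp", "sn", "ip"),
                 seed = seeds[["phaseSo"]], label = "self-organization",
                 snapshotEvery = 500L)
  trStream <- sampleStimulusStream(spec, phaseLengths[["train"]],
                                   seed = seeds[["streamTrain"]])
  tr <- runPhase(so$state, trStream, plasticity = "ip",
                 seed = seeds[["phaseTrain"]], label = "evoked")
  te <- runPhase(tr$state, length = phaseLengths[["test"]],
                 plasticity = "ip", seed = seeds[["phaseTest"]],
                 label = "spontaneous")
  structure(list(preset = "sequence_priors", state = te$state,
                 inputMap = map, params = params, priorA = priorA,
                 recordings = list(selfOrganization = so$recording,
                                   evoked = tr$recording,
                                   spontaneous = te$recording),
                 trainTrials = trStream$trials,
                 snapshots = so$snapshots),
            class = "ExperimentResult")
}

.runInference <- function(params, seeds, phaseLengths, priorA, plasticity,
                          fGrid) {
  if (params@tIMax != 1) {
    params@tIMax <- 1
  }
  alphabet <- c("A", "B", "X")
  map <- buildInputMap(alphabet, params, disjointLetters = c("A", "B"),
                       seed = seeds[["map"]])
  state <- initNetwork(params, map, seed = seeds[["net"]])
  spec <- taskSpec(c("AXXX", "BXXX"), priors = c(priorA, 1 - priorA),
                   blankInterval = c(10L, 15L), phaseLengths = phaseLengths)
  so <- runPhase(state,
                 sampleStimulusStream(spec, phaseLengths[["plastic"]],
                                      seed = seeds[["streamSo"]]),
                 plasticity = plasticity,
                 seed = seeds[["phaseSo"]], label = "self-organization",
                 snapshotEvery = 500L)
  trStream <- sampleStimulusStream(spec, phaseLengths[["train"]],
                                   seed = seeds[["streamTrain"]])
  tr <- runPhase(so$state, trStream, plasticity = "ip",
                 seed = seeds[["phaseTrain"]], label = "training")
  teStream <- inferenceTestStream(map, phaseLengths[["test"]],
                                  fGrid = fGrid,
                                  seed = seeds[["streamTest"]])
  te <- runPhase(tr$state, teStream, plasticity = "ip",
                 seed = seeds[["phaseTest"]], label = "testing")
  readout <- fitDecisionReadout(tr$recording, trStream$trials,
                                seed = seeds[["readout"]])
  decisions <- decisionTrace(readout, te$recording, teStream$trials)
  structure(list(preset = "inference", state = te$state, inputMap = map,
                 params = params, priorA = priorA,
                 recordings = list(selfOrganization = so$recording,
                                   training = tr$recording,
                                   testing = te$recording),
                 trainTrials = trStream$trials,
                 testTrials = teStream$trials,
                 readout = readout, decisions = decisions,
                 snapshots = so$snapshots),
            class = "ExperimentResult")
}

#' Mean response rate over the word steps of each presentation
#'
#' The "sequence magnitude" of a test recording: the mean firing rate over
#' the word steps of every word presentation, computed over the
#' stimulus-driven subpopulation (the units belonging to any input pool of
#' the task alphabet — the model analogue of the sensory-driven neurons an
#' experiment records from).  The same fixed subpopulation is used for every
#' test condition.  Pass `units = NULL` for the whole excitatory population;
#' note that recurrent inhibition largely cancels the recognition effect at
#' the whole-population level, while the driven subpopulation responds more
#' strongly to a sequence presented in its trained order.
#'
#' @param recording a [SpikeRecording-class] from a test phase.
#' @param trials the stream's trial table (`onset` per presentation).
#' @param wordLength number of steps per word.
#' @param units integer vector of units over which to average (default:
#'   all).
#' @return mean rate (spikes per unit per step).
#' @export
sequenceMagnitude <- function(recording, trials, wordLength = 4L,
                              units = NULL) {
  sp <- spikeRaster(recording)
  if (!is.null(units)) sp <- sp[, units, drop = FALSE]
  steps <- unlist(lapply(trials$onset,
                         function(o) seq.int(o, o + wordLength - 1L)))
  steps <- steps[steps <= nrow(sp)]
  mean(sp[steps, , drop = FALSE])
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    out <- c(out, lapply(.permutations(x[-i]), function(p) c(x[i], p)))
  out
}
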