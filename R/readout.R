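#' Fit the decision readout on a training-phase recording
#'
#' Trains two least-squares linear regressions (one per cue class) that map
#' the network's "decision state" — the excitatory state at the first blank
#' step of a trial, i.e. the state evoked by the final mask letter, which is
#' the state present when the blank is shown — to indicator targets for
#' whether cue A or cue B started the trial.  States recorded at the other
#' (letter) steps are included as negative examples with target 0.  Training
#' samples are balanced: an equal number of samples per letter is drawn from
#' the end of the training phase, and each classifier sees an equal number
#' of positive and negative examples regardless of the cue prior (the
#' majority classes are uniformly subsampled).
#'
#' @param recording the training-phase [SpikeRecording-class] (STDP off).
#' @param trials trial table of the training stream (`word`, `onset`).
#' @param wordLength steps per word (cue + mask); the decision state is the
#'   recording row at `onset + wordLength - 1`, the last word step, whose
#'   state coincides with the presentation of the first blank.
#' @param seed seed for the balancing subsample.
#' @return a [LinearReadout-class] with classes `"A"` and `"B"`.
#' @export
fitDecisionReadout <- function(recording, trials, wordLength = 4L,
                               seed = 1L) {
  sp <- spikeRaster(recording)
  letters <- inputLetters(recording)
  decSteps <- trials$onset + wordLength - 1L
  # the decision state must be followed by a blank step
  nextBlank <- c(letters[-1] == "_", TRUE)
  ok <- decSteps <= nrow(sp) & nextBlank[decSteps]
  trials <- trials[ok, , drop = FALSE]
  decSteps <- decSteps[ok]
  cls <- substr(trials$word, 1L, 1L)
  if (length(unique(cls)) < 2L)
    stop("both cue classes must occur in the training data")

  idxA <- decSteps[cls == "A"]
  idxB <- decSteps[cls == "B"]
  nPos <- min(length(idxA), length(idxB))
  set.seed(as.integer(seed))
  takeEnd <- function(idx, n) {
    # prefer samples from the end of training; subsample uniformly if the
    # tail alone cannot balance the classes
    if (length(idx) <= n) idx else sort(sample(idx, n))
  }
  idxA <- takeEnd(idxA, nPos)
  idxB <- takeEnd(idxB, nPos)

  # equally many states per non-blank letter as additional 0-target samples
  # (decision states themselves are excluded from the letter pool)
  letterSteps <- setdiff(which(!letters %in% c("_", "A/B")), decSteps)
  letterLab <- letters[letterSteps]
  perLetter <- max(1L, floor(nPos / max(1L, length(unique(letterLab)))))
  idxL <- unlist(lapply(split(letterSteps, letterLab), function(ix) {
    if (length(ix) <= perLetter) ix else sort(sample(ix, perLetter))
  }), use.names = FALSE)

  allIdx <- c(idxA, idxB, idxL)
  X <- cbind(sp[allIdx, , drop = FALSE], 1)
  isA <- c(rep(1, length(idxA)), rep(0, length(idxB) + length(idxL)))
  isB <- c(rep(0, length(idxA)), rep(1, length(idxB)),
           rep(0, length(idxL)))
  W <- MASS::ginv(X) %*% cbind(A = isA, B = isB)
  colnames(W) <- c("A", "B")
  new("LinearReadout", weights = W, classes = c("A", "B"))
}

#' Network decision from a readout
#'
#' Applies the linear readout to a decision state and returns the class with
#' the larger output; exact ties are broken towards the first class (`"A"`).
#'
#' @param readout a [LinearReadout-class].
#' @param state binary excitatory state vector (or a matrix of states, one
#'   per row).
#' @return character vector of decisions.
#' @examples
#' r <- new("LinearReadout", weights = cbind(A = c(1, 0), B = c(0.5, 0)),
#'          classes = c("A", "B"))
#' decide(r, c(1))
#' @export
decide <- function(readout, state) {
  if (is.null(dim(state))) state <- matrix(state, nrow = 1L)
  out <- cbind(state, 1) %*% readout@weights
  readout@classes[max.col(out, ties.method = "first")]
}

#' Decision trace over the testing phase
#'
#' Evaluates the decision readout at the first blank step of every test
#' trial.
#'
#' @param readout a [LinearReadout-class].
#' @param recording the testing-phase [SpikeRecording-class].
#' @param trials test trial table with columns `fA` and `decisionStep` (from
#'   [inferenceTestStream()]).
#' @return data frame with one row per trial: `fA`, `onset`, `decisionStep`,
#'   `decision`.
#' @export
decisionTrace <- function(readout, recording, trials) {
  sp <- spikeRaster(recording)
  keep <- trials$decisionStep <= nrow(sp)
  trials <- trials[keep, , drop = FALSE]
  dec <- decide(readout, sp[trials$decisionStep, , drop = FALSE])
  data.frame(fA = trials$fA, onset = trials$onset,
             decisionStep = trials$decisionStep, decision = dec)
}

#' Fraction of A-decisions per ambiguity fraction
#'
#' @param decisions a decision trace from [decisionTrace()].
#' @return data frame with columns `fA`, `fractionA`, `nTrials`.
#' @export
decisionCurve <- function(decisions) {
  agg <- stats::aggregate(decision ~ fA, data = decisions,
                          FUN = function(d) mean(d == "A"))
  n <- stats::aggregate(decision ~ fA, data = decisions, FUN = length)
  data.frame(fA = agg$fA, fractionA = agg$decision, nTrials = n$decision)
}

#' Cut a recording into stimulus-aligned trials
#'
#' @param recording a [SpikeRecording-class].
#' @param trials trial table with an `onset` column (step index of the cue).
#' @param pre,post steps kept before and after the onset row.  Row
#'   `onset - 1` of the recording holds the last pre-stimulus state, row
#'   `onset` the first evoked state.
#' @param inputMask logical vector marking units with direct sensory input
#'   (from [directInputMask()]).
#' @param condition optional character vector of per-trial condition labels
#'   (defaults to `fA` or `word` from the trial table).
#' @return a [TrialTensor-class]; trials that do not fit the window are
#'   dropped.
#' @export
alignTrials <- function(recording, trials, pre = 10L, post = 10L,
                        inputMask = logical(ncol(spikeRaster(recording))),
                        condition = NULL) {
  sp <- spikeRaster(recording)
  keep <- trials$onset - pre >= 1L & trials$onset + post <= nrow(sp)
  trials <- trials[keep, , drop = FALSE]
  if (is.null(condition)) {
    condition <- if (!is.null(trials$fA) && !all(is.na(trials$fA))) {
      as.character(trials$fA)
    } else {
      as.character(trials$word)
    }
  } else {
    condition <- as.character(condition)[keep]
  }
  nT <- nrow(trials)
  len <- pre + post + 1L
  arr <- array(0L, dim = c(nT, len, ncol(sp)))
  for (i in seq_len(nT)) {
    rows <- (trials$onset[i] - pre):(trials$onset[i] + post)
    arr[i, , ] <- sp[rows, ]
  }
  new("TrialTensor", spikes = arr, onset = as.integer(pre + 1L),
      condition = condition, inputMask = inputMask)
}

#' Mask of units receiving direct sensory input
#'
#' @param inputMap an [InputMap-class].
#' @param nExc number of excitatory units.
#' @param letters letters whose pools count as direct input (default: all).
#' @return logical vector of length `nExc`.
#' @export
directInputMask <- function(inputMap, nExc, letters = inputMap@alphabet) {
  mask <- logical(nExc)
  mask[unlist(inputMap@pools[letters], use.names = FALSE)] <- TRUE
  mask
}

#' Predict evoked activity from the pre-stimulus spontaneous state
#'
#' For every post-onset offset, fits a least-squares linear map from the
#' stimulus condition (one indicator regressor per condition) together with
#' the excitatory state immediately before stimulus onset (plus a bias
#' regressor) to the evoked state at that offset, pooling the trials of all
#' conditions in one regression.  Reported is the mean Pearson correlation
#' between predicted and actual states, computed per trial over units and
#' then averaged over all trials.  With `shuffle = TRUE` the pre-stimulus
#' states are permuted across trials within each condition, which preserves
#' their statistics but severs their relation to the specific trial; the
#' condition and bias regressors are kept, so the shuffled baseline still
#' captures the stimulus-locked average response.
#'
#' @param tensor a [TrialTensor-class] (conditions taken from its labels).
#' @param offsets post-onset offsets `Dt >= 0`; offset `Dt` predicts the
#'   state at `onset - 1 + Dt`.
#' @param shuffle permute pre-stimulus states across trials within condition.
#' @param seed seed for the shuffle.
#' @return data frame with columns `offset`, `correlation`, `shuffled`.
#' @export
predictEvokedActivity <- function(tensor, offsets = 0:8, shuffle = FALSE,
                                  seed = 1L) {
  arr <- tensor@spikes
  onset <- tensor@onset
  cond <- factor(tensor@condition)
  set.seed(as.integer(seed))
  pre <- arr[, onset - 1L, , drop = TRUE]
  if (shuffle) {
    for (cc in levels(cond)) {
      sel <- which(cond == cc)
      pre[sel, ] <- pre[sel[sample(length(sel))], , drop = FALSE]
    }
  }
  condReg <- if (nlevels(cond) > 1L) {
    stats::model.matrix(~ 0 + cond)
  } else {
    NULL
  }
  X <- cbind(pre, condReg, 1)
  if (nrow(X) < ncol(X))
    warning("fewer trials than regressors; fit is underdetermined ",
            "and solved by pseudoinverse", call. = FALSE)
  Xp <- MASS::ginv(X)
  corByOffset <- vapply(offsets, function(dt) {
    Y <- arr[, onset - 1L + dt, , drop = TRUE]
    pred <- X %*% (Xp %*% Y)
    cr <- vapply(seq_len(nrow(Y)), function(i) {
      if (stats::sd(Y[i, ]) == 0 || stats::sd(pred[i, ]) == 0) NA_real_
      else stats::cor(pred[i, ], Y[i, ])
    }, numeric(1))
    mean(cr, na.rm = TRUE)
  }, numeric(1))
  data.frame(offset = offsets, correlation = corByOffset,
             shuffled = shuffle)
}

#' Predict network decisions from activity around stimulus onset
#'
#' Splits the trials of every ambiguity class into two halves, trains a
#' separate linear readout per (class, offset) on the first half to predict
#' the network's decision from the state at that offset, and reports the
#' agreement with the actual decisions on the held-out half.  The shuffled
#' baseline permutes the states across trials within class; its bias term
#' lets it exploit any decision bias, so it may exceed 50%.
#'
#' @param tensor a [TrialTensor-class] of test trials.
#' @param decisions character vector of network decisions, one per trial of
#'   `tensor`.
#' @param offsets offsets relative to onset (0 = first evoked state, negative
#'   = pre-stimulus spontaneous states).
#' @param shuffle permute states across trials within class.
#' @param minTrials classes with fewer trials are excluded with a warning.
#' @param seed seed for the split and the shuffle.
#' @return data frame with columns `class`, `offset`, `accuracy`, `shuffled`.
#' @export
predictDecisions <- function(tensor, decisions, offsets = -5:5,
                             shuffle = FALSE, minTrials = 10L, seed = 1L) {
  stopifnot(length(decisions) == dim(tensor@spikes)[1])
  arr <- tensor@spikes
  onset <- tensor@onset
  set.seed(as.integer(seed))
  out <- list()
  for (cc in unique(tensor@condition)) {
    sel <- which(tensor@condition == cc)
    if (length(sel) < minTrials) {
      warning("ambiguity class ", cc, " has fewer than ", minTrials,
              " trials and is excluded", call. = FALSE)
      next
    }
    half <- floor(length(sel) / 2)
    trainIx <- sel[seq_len(half)]
    testIx <- sel[(half + 1):length(sel)]
    decTrain <- decisions[trainIx]
    decTest <- decisions[testIx]
    for (dt in offsets) {
      tcol <- onset + dt
      if (tcol < 1L || tcol > dim(arr)[2]) next
      Xtr <- arr[trainIx, tcol, , drop = TRUE]
      Xte <- arr[testIx, tcol, , drop = TRUE]
      if (shuffle) {
        Xtr <- Xtr[sample(nrow(Xtr)), , drop = FALSE]
        Xte <- Xte[sample(nrow(Xte)), , drop = FALSE]
      }
      Xtr <- cbind(Xtr, 1)
      Y <- cbind(A = as.numeric(decTrain == "A"),
                 B = as.numeric(decTrain == "B"))
      W <- MASS::ginv(Xtr) %*% Y
      pred <- cbind(Xte, 1) %*% W
      predCls <- c("A", "B")[max.col(pred, ties.method = "first")]
      out[[length(out) + 1L]] <- data.frame(
        class = cc, offset = dt,
        accuracy = mean(predCls == decTest), shuffled = shuffle)
    }
  }
  do.call(rbind, out)
}
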