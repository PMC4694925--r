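# Synthetic inference-task recording whose decision states are linearly
# separable: unit 1 codes cue A, unit 2 codes cue B; all other activity is
# i.i.d. noise.
separableRecording <- function(nTrials = 60L, nUnits = 30L, seed = 1L,
                               flip = 0) {
  set.seed(seed)
  word <- sample(c("AXXX", "BXXX"), nTrials, replace = TRUE)
  trialLen <- 5L
  sp <- matrix(rbinom(nTrials * trialLen * nUnits, 1, 0.1),
               nTrials * trialLen, nUnits)
  letters <- rep(c("A", "X", "X", "X", "_"), nTrials)
  onsets <- seq(1L, by = trialLen, length.out = nTrials)
  letters[onsets] <- substr(word, 1, 1)
  # decision state: the row of the final mask letter (the state present
  # when the first blank is shown)
  dec <- onsets + 3L
  sp[dec, 1] <- as.integer(word == "AXXX")
  sp[dec, 2] <- as.integer(word == "BXXX")
  if (flip > 0) {
    ix <- sample(nTrials, round(flip * nTrials))
    sp[dec[ix], 1:2] <- 1L - sp[dec[ix], 1:2]
  }
  list(rec = asRecording(sp, letters = letters),
       trials = data.frame(word = word, onset = onsets),
       decisionSteps = dec)
}

test_that("least-squares readout postdicts separable decision states", {
  fx <- separableRecording(seed = 30L)
  ro <- fitDecisionReadout(fx$rec, fx$trials, seed = 1L)
  expect_s4_class(ro, "LinearReadout")
  expect_equal(nrow(ro@weights), 31L)

  # held-out separable states: perfect postdiction
  held <- separableRecording(seed = 31L)
  sp <- spikeRaster(held$rec)
  pred <- decide(ro, sp[held$decisionSteps, ])
  expect_equal(pred, substr(held$trials$word, 1, 1))
})

test_that("decision states without cue information give chance accuracy", {
  # flip = 0.5 destroys the state-target relation entirely: half the
  # decision states carry the opposite cue's signature
  fx <- separableRecording(nTrials = 100L, seed = 32L, flip = 0.5)
  ro <- fitDecisionReadout(fx$rec, fx$trials, seed = 1L)
  held <- separableRecording(nTrials = 200L, seed = 34L, flip = 0.5)
  pred <- decide(ro, spikeRaster(held$rec)[held$decisionSteps, ])
  acc <- mean(pred == substr(held$trials$word, 1, 1))
  expect_lt(abs(acc - 0.5), 0.15)
})

test_that("decide takes the larger readout and breaks ties towards A", {
  ro <- new("LinearReadout",
            weights = cbind(A = c(1, 0, 0), B = c(0, 1, 0)),
            classes = c("A", "B"))
  expect_equal(decide(ro, c(1, 0)), "A")   # outputs (1, 0)
  expect_equal(decide(ro, c(0, 1)), "B")   # outputs (0, 1)
  expect_equal(decide(ro, c(0, 0)), "A")   # tie (0, 0)
  expect_equal(decide(ro, c(1, 1)), "A")   # tie (1, 1)
  expect_equal(decide(ro, rbind(c(1, 0), c(0, 1))), c("A", "B"))
})

test_that("decision traces and curves summarize test trials", {
  fx <- separableRecording(nTrials = 80L, seed = 35L)
  ro <- fitDecisionReadout(fx$rec, fx$trials, seed = 1L)
  trials <- data.frame(fA = rep(c(0, 1), 40), onset = fx$trials$onset,
                       decisionStep = fx$decisionSteps)
  tr <- decisionTrace(ro, fx$rec, trials)
  expect_equal(nrow(tr), 80L)
  dc <- decisionCurve(tr)
  expect_equal(dc$fA, c(0, 1))
  expect_equal(dc$nTrials, c(40L, 40L))
})

test_that("evoked-activity prediction: identity, invariance and signal", {
  set.seed(36)
  nTrials <- 40L
  nUnits <- 15L
  pre <- matrix(rbinom(nTrials * nUnits, 1, 0.4), nTrials, nUnits)
  arr <- array(0L, dim = c(nTrials, 6, nUnits))
  arr[, 1, ] <- pre       # pre-stimulus state (onset - 1)
  arr[, 2, ] <- pre       # offset 1 == copy of the pre state
  ev <- matrix(rbinom(nUnits, 1, 0.5), nTrials, nUnits, byrow = TRUE)
  arr[, 3, ] <- ev        # offset 2: identical evoked response
  arr[, 4, ] <- matrix(rbinom(nTrials * nUnits, 1, 0.3), nTrials)
  tensor <- new("TrialTensor", spikes = arr, onset = 2L,
                condition = rep("c", nTrials), inputMask = logical(nUnits))

  res <- predictEvokedActivity(tensor, offsets = 0:3, seed = 1L)
  # offset 0 predicts the pre-stimulus state from itself
  expect_equal(res$correlation[res$offset == 0], 1, tolerance = 1e-8)
  expect_equal(res$correlation[res$offset == 1], 1, tolerance = 1e-8)

  # identical evoked responses: bias alone suffices, shuffling changes
  # nothing
  sh <- predictEvokedActivity(tensor, offsets = 2, shuffle = TRUE,
                              seed = 2L)
  un <- predictEvokedActivity(tensor, offsets = 2, seed = 2L)
  expect_equal(sh$correlation, un$correlation, tolerance = 1e-8)

  # underdetermined fits warn
  small <- new("TrialTensor", spikes = arr[1:5, , ], onset = 2L,
               condition = rep("c", 5), inputMask = logical(nUnits))
  expect_warning(predictEvokedActivity(small, offsets = 1), "pseudoinverse")
})

test_that("decision prediction is perfect at decision time and dies with
           randomized decisions", {
  set.seed(37)
  nTrials <- 120L
  nUnits <- 12L
  arr <- array(rbinom(nTrials * 8 * nUnits, 1, 0.2),
               dim = c(nTrials, 8, nUnits))
  decisions <- sample(c("A", "B"), nTrials, replace = TRUE)
  # the state at onset + 2 encodes the decision deterministically
  arr[, 6, 1] <- as.integer(decisions == "A")
  arr[, 6, 2] <- as.integer(decisions == "B")
  tensor <- new("TrialTensor", spikes = arr, onset = 4L,
                condition = rep("0.5", nTrials), inputMask = logical(nUnits))

  acc <- predictDecisions(tensor, decisions, offsets = 2L, seed = 1L)
  expect_equal(acc$accuracy, 1)

  # destroyed signal: accuracy falls to the baseline
  accRnd <- predictDecisions(tensor, sample(decisions), offsets = 2L,
                             seed = 1L)
  expect_lt(accRnd$accuracy, 0.7)

  # small classes are excluded with a warning
  tensor2 <- new("TrialTensor", spikes = arr, onset = 4L,
                 condition = c(rep("0.5", 115), rep("0.9", 5)),
                 inputMask = logical(nUnits))
  expect_warning(predictDecisions(tensor2, decisions, offsets = 2L,
                                  seed = 1L),
                 "excluded")
})

test_that("trial alignment windows and masks are honoured", {
  sp <- matrix(rbinom(300 * 10, 1, 0.2), 300, 10)
  rec <- asRecording(sp)
  trials <- data.frame(word = rep("AXXX", 5),
                       onset = c(3L, 50L, 100L, 200L, 298L), fA = NA)
  tensor <- alignTrials(rec, trials, pre = 5L, post = 5L,
                        inputMask = c(TRUE, rep(FALSE, 9)))
  # first and last trials do not fit the window
  expect_equal(dim(tensor@spikes), c(3L, 11L, 10L))
  expect_equal(tensor@onset, 6L)
  expect_equal(tensor@spikes[1, 6, ], sp[50, ])
  expect_equal(tensor@spikes[1, 1, ], sp[45, ])
})
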