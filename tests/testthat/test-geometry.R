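test_that("Hamming distances match direct counting", {
  set.seed(20)
  a <- matrix(rbinom(60, 1, 0.5), 6, 10)
  b <- matrix(rbinom(40, 1, 0.5), 4, 10)
  d <- hammingDistances(a, b)
  for (i in 1:6) for (j in 1:4)
    expect_equal(d[i, j], sum(a[i, ] != b[j, ]))
})

test_that("PCA projection concentrates variance of low-rank states", {
  set.seed(21)
  # states on a 3-dimensional affine lattice
  basis <- matrix(rbinom(3 * 40, 1, 0.5), 3, 40)
  coef <- matrix(sample(0:1, 300, replace = TRUE), 100, 3)
  states <- coef %*% basis
  pr <- pcaProject(states, states[1:10, ])
  expect_gt(sum(pr$explained[1:3]), 1 - 1e-10)
  expect_equal(dim(pr$evoked), c(100L, 3L))
  expect_equal(dim(pr$spontaneous), c(10L, 3L))
  expect_error(pcaProject(states[1:2, ]), "at least")
})

test_that("nonmetric MDS recovers planar configurations and duplicates", {
  set.seed(22)
  pts <- cbind(runif(20), runif(20))
  fit <- nonmetricMds(dist(pts))
  expect_lt(fit$stress, 0.01)

  # binary duplicates collapse to coincident embedding coordinates
  states <- matrix(rbinom(30 * 20, 1, 0.3), 30, 20)
  states[11:20, ] <- states[1:10, ]
  out <- mdsOutline(states[1:10, ], states[11:20, ], states[21:30, ],
                    nPoints = 10L, seed = 1L)
  expect_equal(out$points[out$points$set == "spontaneous", c("x", "y")],
               out$points[out$points$set == "shuffled", c("x", "y")],
               ignore_attr = TRUE)
  expect_true(is.finite(out$stress))
})

test_that("nearest-state distances: verbatim hits and disjoint supports", {
  spont <- diag(1L, 6)[1:3, ]
  evoked <- rbind(spont[1, ], spont[2, ])
  shuff <- diag(1L, 6)[4:6, ]
  d <- nearestStateDistances(evoked, spont, shuff)
  expect_equal(d$dSpont, c(0, 0))
  # k-sparse one-hot states with disjoint support differ in 2k entries
  expect_equal(d$dShuff, c(2, 2))
})

test_that("KL divergence of pattern distributions behaves like a divergence", {
  set.seed(23)
  sp <- matrix(rbinom(5000 * 20, 1, 0.1), 5000, 20)
  recA <- asRecording(sp)
  expect_equal(klEvokedVsSpontaneous(recA, recA, nUnits = 8L, seed = 1L), 0)

  # empty recordings: prior-only distributions are identical
  empty <- asRecording(matrix(0L, 0, 20))
  expect_equal(klEvokedVsSpontaneous(empty, empty, nUnits = 8L, seed = 1L),
               0)

  # differing rate structure gives strictly positive divergence
  spB <- matrix(rbinom(5000 * 20, 1, 0.3), 5000, 20)
  kl <- klEvokedVsSpontaneous(recA, asRecording(spB), nUnits = 8L,
                              units = 1:8)
  expect_gt(kl, 0)

  expect_error(klEvokedVsSpontaneous(recA, recA, nUnits = 25L), "refused")
  expect_error(
    klEvokedVsSpontaneous(recA, asRecording(spB[1:100, ]), nUnits = 8L),
    "equal length")
})

test_that("pattern dictionaries balance letters and label by nearest state", {
  sp <- rbind(diag(1L, 8), diag(1L, 8))[1:12, ]
  letters <- rep(c("A", "B", "C", "_"), 3)
  rec <- asRecording(sp, letters = letters)
  dict <- patternDictionary(rec, n = 12L)
  expect_true(all(table(dict$letters) == min(table(dict$letters))))
  expect_false("_" %in% dict$letters)

  # exact match takes the matching letter
  lab <- assignLetters(dict, dict$states[1, , drop = FALSE])
  expect_equal(lab, dict$letters[1])

  # equidistant state: deterministic tie-break to the alphabetically first
  dict2 <- list(states = rbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L)),
                letters = c("B", "A"))
  tie <- assignLetters(dict2, matrix(c(0L, 0L, 1L, 0L), 1))
  expect_equal(tie, "A")
  expect_error(assignLetters(list(states = matrix(0L, 0, 4),
                                  letters = character()), sp),
               "empty")
})

test_that("word and letter frequencies count decoded streams correctly", {
  labels <- strsplit("ABCDABCDEFGH", "")[[1]]
  wf <- wordLetterFrequencies(labels, c("ABCD", "EFGH", "DCBA", "HGFE"))
  expect_equal(unname(wf$wordFrequencies),
               c(2 / 3, 1 / 3, 0, 0))
  expect_equal(unname(wf$letterFrequencies[c("A", "E")]),
               c(2 / 12, 1 / 12))

  none <- wordLetterFrequencies(c("A", "A", "B"), c("ABCD", "EFGH"))
  expect_true(all(none$wordFrequencies == 0))
  expect_true(attr(none$wordFrequencies, "noWords"))
})

test_that("SVD prediction recovers a planted cyclic transition structure", {
  # four one-letter populations of 5 units each; W maps each population
  # onto the next one in the cycle A -> B -> C -> D -> A
  n <- 20
  pools <- split(1:n, rep(1:4, each = 5))
  w <- matrix(0, n, n)
  for (k in 1:4) {
    from <- pools[[k]]
    to <- pools[[k %% 4 + 1]]
    w[to, from] <- 1 / 5
  }
  states <- matrix(0L, 4, n)
  for (k in 1:4) states[k, pools[[k]]] <- 1L
  dict <- list(states = states, letters = c("A", "B", "C", "D"))
  pred <- svdTransitionPrediction(w, dict)
  expect_equal(pred["A", "B"], 1)
  expect_equal(pred["B", "C"], 1)
  expect_equal(pred["C", "D"], 1)
  expect_equal(pred["D", "A"], 1)
  expect_true(all(abs(rowSums(pred) - 1) < 1e-12))

  # identity-like within-pool matrix: self-transitions dominate
  wSelf <- matrix(0, n, n)
  for (k in 1:4) wSelf[pools[[k]], pools[[k]]] <- 1 / 5
  predSelf <- svdTransitionPrediction(wSelf, dict)
  expect_true(all(diag(predSelf) >= 0.99))

  expect_error(svdTransitionPrediction(matrix(0, 4, 4), dict), "zero")
})

test_that("empirical transitions are row-stochastic counts", {
  tr <- empiricalTransitions(rep(c("A", "B"), 10))
  expect_equal(tr["A", "B"], 1)
  expect_equal(tr["B", "A"], 1)

  set.seed(24)
  lab <- sample(c("A", "B", "C"), 3000, replace = TRUE)
  tr <- empiricalTransitions(lab)
  expect_true(all(abs(tr - 1 / 3) < 0.05))
  expect_true(all(abs(rowSums(tr) - 1) < 1e-12))
})

test_that("time-shuffling preserves rates and destroys timing", {
  set.seed(25)
  sp <- matrix(rbinom(2000 * 10, 1, 0.2), 2000, 10)
  sh <- shuffleSpikeTrains(sp, seed = 2L)
  expect_equal(colSums(sh), colSums(sp))
  expect_false(identical(sh, sp))
})
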