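# Brute-force oracle: posterior from the vector-level Naive Bayes.  All
# 2^10 x 2^10 evidence-vector pairs are enumerated, their likelihoods
# accumulated by count pair, and the posterior computed from the grouped
# sums.  This never passes through the count-form expression under test.
bruteForcePosteriorTable <- function(theta1, theta0, priorA, n = 10L) {
  vecs <- as.matrix(expand.grid(rep(list(0:1), n)))
  counts <- rowSums(vecs)
  likStim <- apply(vecs, 1, function(v) prod(ifelse(v == 1, theta1,
                                                    1 - theta1)))
  likSilent <- apply(vecs, 1, function(v) prod(ifelse(v == 1, 1 - theta0,
                                                      theta0)))
  # under A: a-pool stimulated, b-pool silent; under B the reverse
  jointA <- outer(likStim, likSilent)   # [a-vector, b-vector]
  jointB <- outer(likSilent, likStim)
  numA <- priorA * tapply(jointA, list(counts[row(jointA)],
                                       counts[col(jointA)]), sum)
  numB <- (1 - priorA) * tapply(jointB, list(counts[row(jointB)],
                                             counts[col(jointB)]), sum)
  numA / (numA + numB)
}

test_that("count-form posterior matches the brute-force vector enumeration", {
  set.seed(42)
  nSettings <- 12L
  for (k in seq_len(nSettings)) {
    th1 <- runif(1, 0.05, 0.95)
    th0 <- runif(1, 0.05, 0.95)
    pr <- runif(1, 0.05, 0.95)
    ch <- channelParams(th1, th0, priorA = pr)
    oracle <- bruteForcePosteriorTable(th1, th0, pr)
    ours <- outer(0:10, 0:10, function(a, b) posteriorGivenCounts(ch, a, b))
    expect_lt(max(abs(ours - oracle)), 1e-12)
  }
})

test_that("posterior respects noiseless and symmetric channels", {
  expect_equal(posteriorGivenCounts(channelParams(1, 1), 10, 0), 1)
  expect_equal(posteriorGivenCounts(channelParams(1, 1, priorA = 0.5), 0, 10),
               0)
  # symmetric evidence with any channel and flat prior is uninformative
  for (na in 0:10)
    expect_equal(
      posteriorGivenCounts(channelParams(0.7, 0.3, priorA = 0.5), na, na),
      0.5)
  expect_error(posteriorGivenCounts(channelParams(0.5, 0.5), 11, 0),
               "counts")
})

test_that("count distributions are exact convolutions of the two binomials", {
  ch <- channelParams(1, 1)
  d <- countDistribution(ch, 1)
  expect_equal(d$pA, c(rep(0, 10), 1))
  expect_equal(d$pB, c(1, rep(0, 10)))

  ch <- channelParams(0.85, 0.45)
  for (f in seq(0, 1, by = 0.1)) {
    d <- countDistribution(ch, f)
    expect_equal(sum(d$pA), 1, tolerance = 1e-12)
    expect_equal(sum(d$pB), 1, tolerance = 1e-12)
  }
  expect_error(countDistribution(ch, 0.25), "multiple")

  # Monte-Carlo oracle at f = 0.5: each cell within 3 standard errors
  set.seed(7)
  nMc <- 1e6
  na <- rbinom(nMc, 5, 0.85) + rbinom(nMc, 5, 1 - 0.45)
  emp <- tabulate(na + 1L, nbins = 11L) / nMc
  d <- countDistribution(ch, 0.5)
  se <- sqrt(d$pA * (1 - d$pA) / nMc)
  expect_true(all(abs(emp - d$pA) <= 3 * se + 1e-12))
})

test_that("posterior curve equals the Monte-Carlo expectation of Eq-style
           sampling", {
  ch <- channelParams(0.85, 0.45, priorA = 0.33)
  pc <- posteriorCurve(ch)
  set.seed(8)
  nMc <- 1e6
  for (f in c(0.2, 0.5, 0.8)) {
    k <- round(10 * f)
    na <- rbinom(nMc, k, 0.85) + rbinom(nMc, 10 - k, 1 - 0.45)
    nb <- rbinom(nMc, 10 - k, 0.85) + rbinom(nMc, k, 1 - 0.45)
    mc <- mean(posteriorGivenCounts(ch, na, nb))
    se <- sd(posteriorGivenCounts(ch, na, nb)) / sqrt(nMc)
    expect_lt(abs(pc@pA[match(f, pc@fGrid)] - mc), 3 * se)
  }
})

test_that("posterior curve symmetry, monotonicity and complement", {
  # flat prior, informative channel: p(A | 0.5) = 0.5 and curve increasing
  pc <- posteriorCurve(channelParams(0.8, 0.6, priorA = 0.5))
  expect_equal(pc@pA[pc@fGrid == 0.5], 0.5, tolerance = 1e-12)
  expect_true(all(diff(pc@pA) > 0))
  expect_equal(pc@neutralF, 0.5, tolerance = 1e-12)

  # uninformative channel: the curve is flat at the prior
  pc <- posteriorCurve(channelParams(0.5, 0.5, priorA = 0.3))
  expect_equal(pc@pA, rep(0.3, 11), tolerance = 1e-12)
  expect_true(pc@neutralAtBoundary)

  # prior favouring B moves the neutral fraction above 0.5
  pc <- posteriorCurve(channelParams(0.85, 0.45, priorA = 0.33))
  expect_gt(pc@neutralF, 0.5)

  # p(A | f_A) + p(B | f_A) = 1: swapping the roles of A and B mirrors the
  # curve
  for (pr in c(0.2, 0.5, 0.7)) {
    a <- posteriorCurve(channelParams(0.85, 0.45, priorA = pr))@pA
    b <- posteriorCurve(channelParams(0.85, 0.45, priorA = 1 - pr))@pA
    expect_equal(a, rev(1 - b), tolerance = 1e-12)
  }

  # monotone whenever theta1 > 1 - theta0, over random settings
  set.seed(9)
  for (k in 1:20) {
    th1 <- runif(1)
    th0 <- runif(1, 1 - th1, 1)
    pc <- posteriorCurve(channelParams(th1, th0, priorA = runif(1, 0.05,
                                                                0.95)))
    expect_true(all(diff(pc@pA) >= -1e-12))
  }
})

test_that("grid search recovers channel parameters from synthetic curves", {
  priors <- seq(0.1, 0.9, by = 0.1)
  curves <- do.call(rbind, lapply(priors, function(p) {
    pc <- posteriorCurve(channelParams(0.85, 0.45, priorA = p))
    data.frame(prior = p, fA = pc@fGrid, fractionA = pc@pA)
  }))
  fit <- fitChannelParams(curves)
  expect_equal(fit$theta1, 0.85)
  expect_equal(fit$theta0, 0.45)
  expect_lt(fit$fitError, 1e-20)

  # constant curves at the prior: every uninformative pair (theta1 = 1 -
  # theta0) fits exactly; the documented tie-break picks the largest theta1
  flat <- do.call(rbind, lapply(c(0.3, 0.5, 0.7), function(p)
    data.frame(prior = p, fA = seq(0, 1, 0.1), fractionA = p)))
  fit <- fitChannelParams(flat)
  expect_lt(fit$fitError, 1e-20)
  expect_equal(fit$theta1 + fit$theta0, 1)
  expect_equal(fit$theta1, 0.95)
  expect_error(fitChannelParams(flat[0, ]), "empty")
})
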