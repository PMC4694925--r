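#' Construct noisy-channel parameters
#'
#' @param theta1 probability that a stimulated input unit registers (correct
#'   transmission of a stimulus).
#' @param theta0 probability that an unstimulated unit stays silent (correct
#'   transmission of a non-stimulus).
#' @param nUnits input pool size per cue.
#' @param priorA prior probability of cue A.
#' @return a [ChannelParams-class].
#' @examples
#' channelParams(0.85, 0.45, priorA = 1 / 3)
#' @export
channelParams <- function(theta1, theta0, nUnits = 10L, priorA = 0.5) {
  new("ChannelParams", theta1 = theta1, theta0 = theta0,
      nUnits = as.integer(nUnits), priorA = priorA)
}

# k * log(p) with the convention 0 * log(0) = 0
.xlogp <- function(k, p) ifelse(k == 0, 0, k * log(p))

#' Posterior probability of cue A given evidence counts
#'
#' The Naive Bayes posterior `p(A | n_a, n_b)` for observing `n_a` active
#' units in the A pool and `n_b` in the B pool, under the noisy-channel
#' likelihoods `p(a_i = 1 | A) = theta1`, `p(b_i = 1 | A) = 1 - theta0` (and
#' symmetrically for B).  Computed in log space; the binomial coefficients
#' cancel between numerator and denominator.
#'
#' @param ch a [ChannelParams-class].
#' @param nA,nB evidence counts in `0 .. nUnits` (vectorized).
#' @return posterior probabilities `p(A | nA, nB)`.
#' @examples
#' posteriorGivenCounts(channelParams(1, 1), 10, 0)
#' @export
posteriorGivenCounts <- function(ch, nA, nB) {
  n <- ch@nUnits
  if (any(nA < 0 | nA > n | nB < 0 | nB > n))
    stop("counts must lie in 0 .. nUnits")
  logLA <- .xlogp(nA, ch@theta1) + .xlogp(n - nA, 1 - ch@theta1) +
    .xlogp(nB, 1 - ch@theta0) + .xlogp(n - nB, ch@theta0)
  logLB <- .xlogp(nB, ch@theta1) + .xlogp(n - nB, 1 - ch@theta1) +
    .xlogp(nA, 1 - ch@theta0) + .xlogp(n - nA, ch@theta0)
  la <- log(ch@priorA) + logLA
  lb <- log(1 - ch@priorA) + logLB
  m <- pmax(la, lb)
  exp(la - m) / (exp(la - m) + exp(lb - m))
}

#' Evidence-count distributions for an ambiguous cue
#'
#' With a fraction `fA` of the A pool stimulated (and `1 - fA` of the B
#' pool), the observed counts are sums of two independent binomials:
#' `n_a ~ B(n fA, theta1) + B(n - n fA, 1 - theta0)` and `n_b` with the
#' roles of the pools swapped.  Both marginals are computed by exact
#' convolution; `n_a` and `n_b` are independent.
#'
#' @param ch a [ChannelParams-class].
#' @param fA ambiguity fraction, a multiple of `1 / nUnits`.
#' @return list with `pA` and `pB`, the distributions of `n_a` and `n_b`
#'   over `0 .. nUnits`.
#' @export
countDistribution <- function(ch, fA) {
  n <- ch@nUnits
  k <- round(fA * n)
  if (abs(fA * n - k) > 1e-8)
    stop("fA must be a multiple of 1/nUnits")
  conv <- function(nStim, nSilent) {
    p1 <- stats::dbinom(0:nStim, nStim, ch@theta1)
    p0 <- stats::dbinom(0:nSilent, nSilent, 1 - ch@theta0)
    out <- numeric(n + 1)
    for (i in 0:nStim)
      out[(i + 1):(i + nSilent + 1)] <-
        out[(i + 1):(i + nSilent + 1)] + p1[i + 1] * p0
    out
  }
  list(pA = conv(k, n - k), pB = conv(n - k, k))
}

#' Exact posterior decision curve
#'
#' The model's probability of deciding "A" for each ambiguity fraction,
#' `p(A | f_A) = < p(A | n_a, n_b) >`, computed exactly by enumerating the
#' `(nUnits + 1)^2` count pairs under their independent distributions.  The
#' neutral fraction — where the curve crosses 0.5 — is found by linear
#' interpolation between grid points; if the curve never crosses 0.5 the
#' nearest grid boundary is reported and flagged.
#'
#' @param ch a [ChannelParams-class].
#' @param fGrid ambiguity fractions (multiples of `1 / nUnits`).
#' @return a [PosteriorCurve-class].
#' @examples
#' pc <- posteriorCurve(channelParams(0.85, 0.45, priorA = 0.33))
#' pc@neutralF
#' @export
posteriorCurve <- function(ch, fGrid = (0:ch@nUnits) / ch@nUnits) {
  n <- ch@nUnits
  post <- outer(0:n, 0:n, function(a, b) posteriorGivenCounts(ch, a, b))
  pA <- vapply(fGrid, function(f) {
    d <- countDistribution(ch, f)
    sum(outer(d$pA, d$pB) * post)
  }, numeric(1))
  g <- pA - 0.5
  cross <- which(g[-length(g)] * g[-1] <= 0 &
                   (g[-length(g)] != 0 | g[-1] != 0))
  if (any(g == 0)) {
    neutral <- fGrid[which(g == 0)[1]]
    boundary <- FALSE
  } else if (length(cross)) {
    i <- cross[1]
    neutral <- fGrid[i] + (fGrid[i + 1] - fGrid[i]) *
      (0 - g[i]) / (g[i + 1] - g[i])
    boundary <- FALSE
  } else {
    neutral <- fGrid[which.min(abs(g))]
    boundary <- TRUE
  }
  new("PosteriorCurve", fGrid = fGrid, pA = pA,
      neutralF = neutral, neutralAtBoundary = boundary)
}

#' Fit the channel parameters to measured decision curves
#'
#' Exhaustive grid search over `(theta1, theta0)` (default grid 0.05 to 0.95
#' in steps of 0.05): for every candidate pair the exact posterior curves for
#' all supplied priors are compared to the measured fractions of A-decisions,
#' and the pair minimizing the sum over curves of the mean squared deviation
#' is returned.  The curve family is invariant under
#' `(theta1, theta0) -> (1 - theta0, 1 - theta1)` and under relabelling the
#' two cues, so the minimizer is only unique up to this symmetry; ties
#' (including these exact symmetry copies) are broken towards larger
#' `theta1`, then larger `theta0`, which selects the representative with a
#' mostly-faithful stimulus channel.
#'
#' @param curves data frame with columns `prior`, `fA`, `fractionA`; one
#'   decision curve per distinct prior.
#' @param grid candidate values for both parameters.
#' @param nUnits input pool size.
#' @return list with `theta1`, `theta0`, `fitError` (the minimized summed
#'   MSE), and `errorGrid` (matrix of summed MSEs, theta1 by theta0).
#' @export
fitChannelParams <- function(curves, grid = seq(0.05, 0.95, by = 0.05),
                             nUnits = 10L) {
  if (!nrow(curves)) stop("empty decision curves")
  priors <- sort(unique(curves$prior))
  err <- matrix(NA_real_, length(grid), length(grid),
                dimnames = list(theta1 = grid, theta0 = grid))
  for (i1 in seq_along(grid)) {
    for (i0 in seq_along(grid)) {
      e <- 0
      for (p in priors) {
        sub <- curves[curves$prior == p, , drop = FALSE]
        pc <- posteriorCurve(
          channelParams(grid[i1], grid[i0], nUnits, p), sort(unique(sub$fA)))
        model <- pc@pA[match(sub$fA, pc@fGrid)]
        e <- e + mean((model - sub$fractionA)^2)
      }
      err[i1, i0] <- e
    }
  }
  # The curve family is invariant under (theta1, theta0) -> (1 - theta0,
  # 1 - theta1) and under relabelling A/B, so up to four grid points carry
  # mathematically identical curves; they are tied up to float noise and the
  # documented tie-break (larger theta1, then larger theta0) selects one
  # representative.
  tol <- 1e-9 * (1 + min(err))
  best <- which(err <= min(err) + tol, arr.ind = TRUE)
  best <- best[order(-best[, 1], -best[, 2]), , drop = FALSE][1, ]
  list(theta1 = grid[best[1]], theta0 = grid[best[2]],
       fitError = min(err), errorGrid = err)
}
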