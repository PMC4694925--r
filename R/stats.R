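#' Inter-spike interval statistics
#'
#' Collects the inter-spike intervals of every excitatory unit from a
#' (typically spontaneous) recording, computes the per-neuron coefficient of
#' variation CV = sd/mean of the ISIs (neurons with fewer than `minIsi`
#' intervals are excluded), and fits an exponential to the pooled ISI
#' distribution by maximum likelihood after discarding very small intervals
#' (the `cutoff`, default 2 steps, below which the discrete dynamics deviate
#' from the exponential regime).
#'
#' @param recording a [SpikeRecording-class].
#' @param minIsi minimum number of ISIs for a neuron to contribute a CV.
#' @param cutoff ISIs at or below this value are excluded from the
#'   exponential fit.
#' @return list with `isi` (per-neuron ISI lists), `cv` (per-neuron CVs),
#'   `rate` (fitted exponential rate of the shifted pooled ISIs),
#'   `nExcluded` (neurons with too few ISIs, including silent ones).
#' @export
isiCvStats <- function(recording, minIsi = 10L, cutoff = 2) {
  sp <- spikeRaster(recording)
  isi <- lapply(seq_len(ncol(sp)), function(i) diff(which(sp[, i] == 1L)))
  enough <- vapply(isi, length, 0L) >= minIsi
  cv <- vapply(isi[enough], function(d) stats::sd(d) / mean(d), numeric(1))
  pooled <- unlist(isi, use.names = FALSE)
  pooled <- pooled[pooled > cutoff]
  rate <- if (length(pooled)) 1 / mean(pooled - cutoff) else NA_real_
  list(isi = isi, cv = cv, rate = rate, nExcluded = sum(!enough))
}

#' Fraction of existing excitatory synapses
#'
#' For a [SornState-class], the fraction of strictly positive off-diagonal
#' entries of the recurrent weight matrix; for a list of weight matrices (or
#' masks), the corresponding time series; for the snapshot data frame
#' returned by [runPhase()], its recorded trace.
#'
#' @param x a [SornState-class], a list of matrices, or a snapshot data
#'   frame.
#' @return numeric scalar or vector of connection fractions.
#' @export
connectionFraction <- function(x) {
  frac <- function(w) {
    n <- nrow(w)
    (sum(w > 0) - sum(diag(w) > 0)) / (n * (n - 1))
  }
  if (is(x, "SornState")) return(frac(x@wEE))
  if (is.data.frame(x)) return(x$connectionFraction)
  if (is.list(x)) return(vapply(x, frac, numeric(1)))
  stop("unsupported input")
}

#' Lognormal fit to the nonzero excitatory weights
#'
#' Maximum-likelihood lognormal fit (closed form on the log weights) with
#' Kolmogorov-Smirnov statistics for both the lognormal fit and, for
#' comparison, a normal fit.
#'
#' @param w a weight matrix or a [SornState-class].
#' @param minWeights minimum number of nonzero weights required.
#' @return list with `meanlog`, `sdlog`, `ks` (KS statistic of the lognormal
#'   fit), `ksNormal` (KS statistic of a normal fit), `n`.
#' @export
fitLognormalWeights <- function(w, minWeights = 100L) {
  if (is(w, "SornState")) w <- w@wEE
  v <- w[w > 0]
  if (length(v) < minWeights)
    stop("need at least ", minWeights, " nonzero weights")
  meanlog <- mean(log(v))
  sdlog <- stats::sd(log(v))
  ks <- suppressWarnings(
    stats::ks.test(v, "plnorm", meanlog = meanlog, sdlog = sdlog))$statistic
  ksn <- suppressWarnings(
    stats::ks.test(v, "pnorm", mean = mean(v), sd = stats::sd(v)))$statistic
  list(meanlog = meanlog, sdlog = sdlog, ks = unname(ks),
       ksNormal = unname(ksn), n = length(v))
}

# windowed spike counts: causal window of `window` steps (current step and
# the window-1 preceding ones, truncated at the trial start)
.windowedCounts <- function(arr, window) {
  d <- dim(arr)
  cs <- apply(arr, c(1, 3), cumsum)          # time x trials x neurons
  cs <- aperm(cs, c(2, 1, 3))
  out <- cs
  if (d[2] > window)
    out[, (window + 1):d[2], ] <- cs[, (window + 1):d[2], ] -
      cs[, 1:(d[2] - window), ]
  out
}

#' Fano factor curve around stimulus onset
#'
#' For every neuron without direct sensory input and every time offset, spike
#' counts in a causal sliding window (default 5 steps) are averaged over
#' trials; the population Fano factor at each offset is the slope of the
#' weighted regression of the count variance on the count mean across
#' neurons, with weights proportional to the inverse asymptotic variance of
#' the variance estimate (which scales as mean^2 / nTrials).  With those
#' weights the slope reduces to the mean variance-to-mean ratio over
#' contributing neurons; neurons with zero mean count at an offset are
#' excluded there.
#'
#' @param tensor a [TrialTensor-class]; trials of all conditions are pooled
#'   unless `byCondition` is set.
#' @param window causal window width in steps.
#' @param byCondition compute a separate curve per condition label.
#' @return data frame with columns `offset` (relative to onset; 0 = first
#'   evoked state), `ff`, `meanRate` (mean windowed count), `n` (points in
#'   the regression), and `condition` when `byCondition`; the attribute
#'   `"window"` stores the window width and `"truncated"` flags offsets whose
#'   window reached past the start of the trial.
#' @export
fanoCurve <- function(tensor, window = 5L, byCondition = FALSE) {
  arr <- tensor@spikes[, , !tensor@inputMask, drop = FALSE]
  counts <- .windowedCounts(arr, window)
  onset <- tensor@onset
  groups <- if (byCondition) unique(tensor@condition) else "all"
  res <- list()
  for (g in groups) {
    sel <- if (byCondition) tensor@condition == g else
      rep(TRUE, dim(arr)[1])
    cg <- counts[sel, , , drop = FALSE]
    mu <- apply(cg, c(2, 3), mean)
    va <- apply(cg, c(2, 3), stats::var)
    ff <- vapply(seq_len(nrow(mu)), function(t) {
      m <- mu[t, ]; v <- va[t, ]
      use <- m > 0
      if (!any(use)) return(NA_real_)
      # weights ~ nTrials / mean^2 collapse the weighted slope to the mean
      # variance/mean ratio
      mean(v[use] / m[use])
    }, numeric(1))
    res[[g]] <- data.frame(
      offset = seq_len(nrow(mu)) - onset,
      ff = ff, meanRate = rowMeans(mu),
      n = vapply(seq_len(nrow(mu)), function(t) sum(mu[t, ] > 0), 0L),
      condition = g)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (!byCondition) out$condition <- NULL
  attr(out, "window") <- window
  attr(out, "truncated") <- seq_len(dim(arr)[2]) - onset < window - 1L
  out
}

#' Mean-matched Fano factor
#'
#' Controls the Fano factor for rate changes: the distributions of windowed
#' mean counts (one point per neuron and condition) are binned per offset,
#' the greatest common distribution (per-bin minimum across offsets) is
#' computed, points are randomly discarded in every bin of every offset until
#' its histogram equals the common one, and the weighted-regression Fano
#' factor is recomputed from the surviving points.  The procedure is repeated
#' over several discard randomizations and averaged.
#'
#' @param tensor a [TrialTensor-class].
#' @param window causal window width.
#' @param binWidth histogram bin width for the mean counts.  The default,
#'   0.005 counts, is on the order of the resolution at which trial-averaged
#'   means are defined (1 / nTrials for typical trial counts), i.e. the
#'   matching is close to exact; at this granularity the procedure discards
#'   a substantial fraction of the data, comparable to the original
#'   mean-matching analyses.
#' @param nIter number of discard randomizations.
#' @param seed seed for the discards.
#' @return data frame with columns `offset`, `ff` (mean-matched), `rawFf`;
#'   attribute `"discardFraction"` gives the overall fraction of
#'   (neuron, condition) points discarded.
#' @export
meanMatchedFano <- function(tensor, window = 5L, binWidth = 0.005,
                            nIter = 10L, seed = 1L) {
  conds <- unique(tensor@condition)
  arr <- tensor@spikes[, , !tensor@inputMask, drop = FALSE]
  counts <- .windowedCounts(arr, window)
  # offsets whose causal window is truncated by the trial start have
  # systematically smaller counts and are excluded from the matching
  offsets <- seq.int(min(window, dim(arr)[2]), dim(arr)[2])
  counts <- counts[, offsets, , drop = FALSE]
  nOff <- length(offsets)
  if (nOff < 2L) stop("need at least 2 offsets")
  # per offset: one (mean, var) point per neuron x condition
  mus <- vas <- vector("list", nOff)
  for (t in seq_len(nOff)) {
    m <- v <- numeric(0)
    for (g in conds) {
      sel <- tensor@condition == g
      cg <- counts[sel, t, , drop = FALSE]
      m <- c(m, apply(cg, 3, mean))
      v <- c(v, apply(cg, 3, stats::var))
    }
    mus[[t]] <- m
    vas[[t]] <- v
  }
  maxMu <- max(unlist(mus))
  breaks <- seq(0, maxMu + binWidth, by = binWidth)
  binOf <- lapply(mus, function(m) findInterval(m, breaks,
                                                rightmost.closed = TRUE))
  histPerOffset <- vapply(binOf, function(b)
    tabulate(b, nbins = length(breaks)), integer(length(breaks)))
  common <- apply(histPerOffset, 1, min)
  if (sum(common) == 0)
    stop("greatest common mean-count distribution is empty")
  set.seed(as.integer(seed))
  ffIter <- matrix(NA_real_, nIter, nOff)
  discarded <- 0
  total <- 0
  for (it in seq_len(nIter)) {
    for (t in seq_len(nOff)) {
      keep <- unlist(lapply(seq_along(common), function(b) {
        ix <- which(binOf[[t]] == b)
        if (length(ix) <= common[b]) ix else sample(ix, common[b])
      }), use.names = FALSE)
      total <- total + length(mus[[t]])
      discarded <- discarded + length(mus[[t]]) - length(keep)
      m <- mus[[t]][keep]
      v <- vas[[t]][keep]
      use <- m > 0
      ffIter[it, t] <- if (any(use)) mean(v[use] / m[use]) else NA_real_
    }
  }
  raw <- vapply(seq_len(nOff), function(t) {
    use <- mus[[t]] > 0
    mean(vas[[t]][use] / mus[[t]][use])
  }, numeric(1))
  out <- data.frame(offset = offsets - tensor@onset,
                    ff = colMeans(ffIter, na.rm = TRUE), rawFf = raw)
  attr(out, "discardFraction") <- discarded / total
  out
}

#' Conditional firing probabilities versus synaptic weight
#'
#' For every existing synapse, the empirical probability that the
#' postsynaptic unit spikes one step after the presynaptic unit spiked,
#' estimated from a spontaneous recording (pairs whose presynaptic unit never
#' spikes are skipped).  The proportionality constant kappa of
#' `p(x_i(t+1) = 1 | x_j(t) = 1) ~ kappa * W_ij` is fitted by least squares
#' through the origin after excluding the saturation regime (weights above
#' the `saturationQuantile`).
#'
#' @param recording a spontaneous [SpikeRecording-class].
#' @param state a [SornState-class] (or a weight matrix) providing the
#'   synapses.
#' @return list with `pairs` (data frame `i`, `j`, `weight`, `prob`),
#'   `kappa`, and `r` (Pearson correlation below saturation).
#' @param saturationQuantile weights above this quantile are excluded from
#'   the kappa fit.
#' @export
conditionalFiringProbabilities <- function(recording, state,
                                           saturationQuantile = 0.95) {
  w <- if (is(state, "SornState")) state@wEE else state
  mask <- if (is(state, "SornState")) state@synapses else w > 0
  sp <- spikeRaster(recording)
  T <- nrow(sp)
  num <- crossprod(sp[2:T, , drop = FALSE], sp[1:(T - 1), , drop = FALSE])
  den <- colSums(sp[1:(T - 1), , drop = FALSE])
  syn <- which(mask & outer(rep(TRUE, nrow(w)), den > 0), arr.ind = TRUE)
  prob <- num[syn] / den[syn[, 2]]
  pairs <- data.frame(i = syn[, 1], j = syn[, 2],
                      weight = w[syn], prob = prob)
  thr <- stats::quantile(pairs$weight, saturationQuantile)
  sub <- pairs[pairs$weight <= thr, , drop = FALSE]
  kappa <- sum(sub$weight * sub$prob) / sum(sub$weight^2)
  r <- if (nrow(sub) > 2 && stats::sd(sub$weight) > 0 &&
           stats::sd(sub$prob) > 0) {
    stats::cor(sub$weight, sub$prob)
  } else NA_real_
  list(pairs = pairs, kappa = kappa, r = r)
}

#' Empirical expected STDP drift per synapse
#'
#' Estimates, from a recording, the expected STDP update
#' `E[dW_ij] = etaStdp * (p(x_i(t+1)=1, x_j(t)=1) - p(x_j(t+1)=1, x_i(t)=1))`
#' for every existing synapse.  In spontaneous activity with intrinsic
#' plasticity at its target rate this drift is approximately proportional to
#' the weight difference `W_ij - W_ji` of the reciprocal pair.
#'
#' @param recording a [SpikeRecording-class].
#' @param state a [SornState-class] (or weight matrix).
#' @param etaStdp STDP learning rate used for scaling.
#' @return data frame with `i`, `j`, `weight`, `reverseWeight`, `drift`.
#' @export
stdpDrift <- function(recording, state, etaStdp = 0.001) {
  w <- if (is(state, "SornState")) state@wEE else state
  mask <- if (is(state, "SornState")) state@synapses else w > 0
  sp <- spikeRaster(recording)
  T <- nrow(sp)
  joint <- crossprod(sp[2:T, , drop = FALSE],
                     sp[1:(T - 1), , drop = FALSE]) / (T - 1)
  syn <- which(mask, arr.ind = TRUE)
  data.frame(i = syn[, 1], j = syn[, 2],
             weight = w[syn], reverseWeight = w[syn[, 2:1, drop = FALSE]],
             drift = etaStdp * (joint[syn] - joint[syn[, 2:1, drop = FALSE]]))
}
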