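#' Pairwise Hamming distances between binary state matrices
#'
#' @param a,b binary matrices with states in rows (same number of columns);
#'   `b` defaults to `a`.
#' @return integer matrix of Hamming distances, `nrow(a)` by `nrow(b)`.
#' @export
hammingDistances <- function(a, b = a) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  # |x - y|_1 for binary vectors: |x| + |y| - 2 x.y
  d <- outer(rowSums(a), rowSums(b), "+") - 2 * tcrossprod(a, b)
  round(d)
}

#' PCA projection of evoked and spontaneous states
#'
#' Principal components are fit on the evoked states only (mean-centered,
#' unscaled); both evoked and spontaneous states are projected into the
#' leading-component subspace.
#'
#' @param evoked binary matrix of evoked states (rows), typically the last
#'   2500 states of the training phase.
#' @param spontaneous binary matrix of spontaneous states.
#' @param nComponents number of leading components to keep.
#' @return list with `evoked` and `spontaneous` projections (rows match the
#'   inputs), `explained` (per-component variance fractions of the evoked
#'   states, all components), and `rotation`.
#' @export
pcaProject <- function(evoked, spontaneous = NULL, nComponents = 3L) {
  if (nrow(evoked) < nComponents)
    stop("need at least nComponents evoked states")
  pc <- stats::prcomp(evoked, center = TRUE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- seq_len(min(nComponents, ncol(pc$rotation)))
  proj <- function(m) {
    sweep(as.matrix(m), 2, pc$center) %*% pc$rotation[, keep, drop = FALSE]
  }
  list(evoked = pc$x[, keep, drop = FALSE],
       spontaneous = if (is.null(spontaneous)) NULL else proj(spontaneous),
       explained = explained,
       rotation = pc$rotation[, keep, drop = FALSE])
}

#' Shuffle each neuron's spike train independently over time
#'
#' Preserves every unit's firing rate while destroying all spike timing.
#'
#' @param states binary matrix, steps by units.
#' @param seed seed for the permutations.
#' @return shuffled matrix of the same dimension.
#' @export
shuffleSpikeTrains <- function(states, seed = 1L) {
  set.seed(as.integer(seed))
  apply(states, 2, sample)
}

#' Nonmetric MDS embedding of the joint state matrix (Kruskal stress-1)
#'
#' @param d a `dist` object or full distance matrix.
#' @param k embedding dimension.
#' @param maxit maximum isoMDS iterations.
#' @return list with `points` (coordinates) and `stress` (Kruskal's
#'   normalized stress-1, in `[0, 1]`).
#' @export
nonmetricMds <- function(d, k = 2L, maxit = 100L) {
  fit <- MASS::isoMDS(stats::as.dist(d), k = k, maxit = maxit, trace = FALSE)
  list(points = fit$points, stress = fit$stress / 100)
}

#' Two-dimensional outline of spontaneous, shuffled and evoked states
#'
#' Embeds a pooled sample of spontaneous states, their time-shuffled
#' versions, and evoked states into two dimensions by nonmetric MDS on the
#' pooled pairwise Hamming-distance matrix, minimizing Kruskal's normalized
#' stress-1.  Exactly duplicated states are collapsed before the fit (isoMDS
#' requires strictly positive dissimilarities) and re-expanded to coincident
#' coordinates afterwards.
#'
#' @param spontaneous,shuffled,evoked binary state matrices; `nPoints` rows
#'   are sampled from each.
#' @param nPoints sample size per set.
#' @param seed seed for the subsampling.
#' @return list with `points` (data frame `x`, `y`, `set`) and `stress`.
#' @export
mdsOutline <- function(spontaneous, shuffled, evoked, nPoints = 150L,
                       seed = 1L) {
  set.seed(as.integer(seed))
  pick <- function(m) {
    if (nrow(m) > nPoints) m[sort(sample.int(nrow(m), nPoints)), ,
                             drop = FALSE] else m
  }
  sets <- list(spontaneous = pick(spontaneous), shuffled = pick(shuffled),
               evoked = pick(evoked))
  pooled <- do.call(rbind, sets)
  lab <- rep(names(sets), vapply(sets, nrow, 0L))
  key <- apply(pooled, 1, paste, collapse = "")
  uix <- !duplicated(key)
  fit <- nonmetricMds(hammingDistances(pooled[uix, , drop = FALSE]))
  coords <- fit$points[match(key, key[uix]), , drop = FALSE]
  list(points = data.frame(x = coords[, 1], y = coords[, 2], set = lab),
       stress = fit$stress)
}

#' Distances from evoked states to the nearest spontaneous states
#'
#' For each evoked state, the Hamming distance to its nearest neighbour in
#' the spontaneous set (`dSpont`) and in the time-shuffled spontaneous set
#' (`dShuff`).
#'
#' @param evoked,spontaneous,shuffled binary state matrices.
#' @return data frame with columns `dSpont` and `dShuff`, one row per evoked
#'   state.
#' @export
nearestStateDistances <- function(evoked, spontaneous, shuffled) {
  stopifnot(nrow(evoked) > 0, nrow(spontaneous) > 0, nrow(shuffled) > 0)
  data.frame(
    dSpont = apply(hammingDistances(evoked, spontaneous), 1, min),
    dShuff = apply(hammingDistances(evoked, shuffled), 1, min))
}

#' KL divergence between evoked and spontaneous pattern distributions
#'
#' Subsamples `nUnits` units, counts the occurrences of each of the
#' `2^nUnits` binary patterns in both recordings with an add-one prior
#' (every pattern starts with one pseudo-observation, which keeps the
#' divergence finite), normalizes, and returns
#' `KL(P_evoked || P_spontaneous)`.  Patterns observed in neither recording
#' contribute exactly zero and are handled in closed form, so only observed
#' patterns are enumerated.
#'
#' @param evokedRec,spontRec [SpikeRecording-class] objects (or bare spike
#'   matrices) of equal length.
#' @param nUnits number of subsampled units (at most 24).
#' @param units optional explicit unit indices (overrides the random draw).
#' @param excludeInitial steps dropped from the start of each recording to
#'   skip re-adaptation transients.
#' @param seed seed for the unit subsample.
#' @return KL divergence in nats (non-negative scalar).
#' @export
klEvokedVsSpontaneous <- function(evokedRec, spontRec, nUnits = 16L,
                                  units = NULL, excludeInitial = 0L,
                                  seed = 1L) {
  if (nUnits > 24L) stop("nUnits > 24 refused (2^nUnits pattern space)")
  ev <- if (is(evokedRec, "SpikeRecording")) spikeRaster(evokedRec) else
    evokedRec
  sq <- if (is(spontRec, "SpikeRecording")) spikeRaster(spontRec) else
    spontRec
  if (excludeInitial > 0L) {
    ev <- ev[-seq_len(excludeInitial), , drop = FALSE]
    sq <- sq[-seq_len(excludeInitial), , drop = FALSE]
  }
  if (nrow(ev) != nrow(sq))
    stop("recordings must have equal length after the initial exclusion")
  if (is.null(units)) {
    set.seed(as.integer(seed))
    units <- sort(sample.int(ncol(ev), nUnits))
  }
  pow <- 2^(seq_along(units) - 1)
  codeE <- as.vector(ev[, units, drop = FALSE] %*% pow)
  codeS <- as.vector(sq[, units, drop = FALSE] %*% pow)
  tot <- 2^length(units)
  denom <- nrow(ev) + tot
  allCodes <- union(codeE, codeS)
  cE <- tabulate(match(codeE, allCodes), nbins = length(allCodes))
  cS <- tabulate(match(codeS, allCodes), nbins = length(allCodes))
  pE <- (cE + 1) / denom
  pS <- (cS + 1) / denom
  # patterns unseen in both recordings have pE == pS and contribute 0
  sum(pE * log(pE / pS))
}

#' Dictionary of labelled evoked patterns
#'
#' Collects the last `n` evoked states of a training recording, drops blank
#' steps, and balances the letters so that each is represented equally often
#' (each letter is downsampled to the least frequent letter's count, keeping
#' the most recent states).
#'
#' @param recording the training-phase [SpikeRecording-class].
#' @param n number of trailing states to consider (default 2500).
#' @return list with `states` (binary matrix) and `letters` (one label per
#'   row), of class `"PatternDictionary"`.
#' @export
patternDictionary <- function(recording, n = 2500L) {
  sp <- spikeRaster(recording)
  lt <- inputLetters(recording)
  tail <- seq.int(max(1L, nrow(sp) - n + 1L), nrow(sp))
  tail <- tail[lt[tail] != "_"]
  lt <- lt[tail]
  minCount <- min(table(lt))
  keep <- unlist(lapply(split(seq_along(tail), lt), function(ix)
    utils::tail(ix, minCount)), use.names = FALSE)
  keep <- sort(keep)
  structure(list(states = sp[tail[keep], , drop = FALSE],
                 letters = lt[keep]),
            class = "PatternDictionary")
}

#' Assign input letters to spontaneous states
#'
#' Each spontaneous state is labelled with the letter of its
#' minimum-Hamming-distance evoked state in the dictionary.  Ties are broken
#' deterministically: first by the smallest letter index (alphabetical order
#' of the dictionary letters), then by the earliest dictionary entry.
#'
#' @param dictionary a pattern dictionary from [patternDictionary()].
#' @param spontaneous binary matrix of spontaneous states.
#' @return character vector of assigned letters, one per spontaneous state.
#' @export
assignLetters <- function(dictionary, spontaneous) {
  if (!length(dictionary$letters)) stop("empty pattern dictionary")
  ord <- order(match(dictionary$letters, sort(unique(dictionary$letters))),
               seq_along(dictionary$letters))
  states <- dictionary$states[ord, , drop = FALSE]
  letters <- dictionary$letters[ord]
  d <- hammingDistances(spontaneous, states)
  letters[max.col(-d, ties.method = "first")]
}

#' Letter and word frequencies of a decoded state sequence
#'
#' @param labels character vector of decoded letters (e.g. from
#'   [assignLetters()]).
#' @param words words to count; word frequencies are the counts of each
#'   word's (non-overlapping) occurrences in the decoded stream, normalized
#'   over the total count of all listed words.
#' @return list with `letterFrequencies` (named vector of empirical letter
#'   fractions) and `wordFrequencies` (named vector over `words`; all-zero
#'   with attribute `noWords = TRUE` when no listed word occurs).
#' @export
wordLetterFrequencies <- function(labels, words) {
  letterFreq <- table(labels) / length(labels)
  stream <- paste(labels, collapse = "")
  counts <- vapply(words, function(w) {
    m <- gregexpr(w, stream, fixed = TRUE)[[1]]
    sum(m > 0)
  }, numeric(1))
  tot <- sum(counts)
  wf <- if (tot > 0) counts / tot else counts
  if (tot == 0) attr(wf, "noWords") <- TRUE
  list(letterFrequencies = c(letterFreq), wordFrequencies = wf)
}

#' Predict letter transition structure from the SVD of the weight matrix
#'
#' In the linearized dynamics `x(t+1) = W x(t)`, each singular triplet
#' `(u_i, sigma_i, v_i)` maps the pattern `v_i` onto `sigma_i u_i`.  Both
#' vectors are matched to input letters by the maximum dot product with the
#' labelled evoked states (evaluating both sign orientations of the pair
#' jointly and keeping the better one), and `sigma_i` is accumulated onto
#' the (letter(v_i) -> letter(u_i)) transition.  Rows are normalized to 1
#' over observed successors.
#'
#' @param w excitatory weight matrix (or [SornState-class]).
#' @param dictionary a labelled pattern dictionary from
#'   [patternDictionary()].
#' @return row-stochastic transition matrix (letters by letters).
#' @export
svdTransitionPrediction <- function(w, dictionary) {
  if (is(w, "SornState")) w <- w@wEE
  if (all(w == 0)) stop("zero weight matrix has no transition structure")
  letters <- sort(unique(dictionary$letters))
  states <- dictionary$states
  sv <- svd(w)
  trans <- matrix(0, length(letters), length(letters),
                  dimnames = list(from = letters, to = letters))
  for (i in seq_along(sv$d)) {
    if (sv$d[i] <= 0) next
    dv <- drop(states %*% sv$v[, i])
    du <- drop(states %*% sv$u[, i])
    if (max(dv) + max(du) >= max(-dv) + max(-du)) {
      from <- dictionary$letters[which.max(dv)]
      to <- dictionary$letters[which.max(du)]
    } else {
      from <- dictionary$letters[which.max(-dv)]
      to <- dictionary$letters[which.max(-du)]
    }
    trans[from, to] <- trans[from, to] + sv$d[i]
  }
  rs <- rowSums(trans)
  trans[rs > 0, ] <- trans[rs > 0, , drop = FALSE] / rs[rs > 0]
  trans
}

#' Empirical first-order letter transitions
#'
#' @param labels character vector of (decoded) letters in temporal order.
#' @return row-stochastic transition matrix over the observed letters.
#' @export
empiricalTransitions <- function(labels) {
  letters <- sort(unique(labels))
  trans <- table(factor(labels[-length(labels)], levels = letters),
                 factor(labels[-1], levels = letters))
  trans <- unclass(trans / pmax(rowSums(trans), 1))
  dimnames(trans) <- list(from = letters, to = letters)
  trans
}
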