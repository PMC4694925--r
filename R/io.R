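#' Read a simulation configuration file
#'
#' The YAML schema mirrors [sornParams()] plus phase lengths and preset
#' options, e.g.:
#'
#' ```yaml
#' params:
#'   nExc: 200
#'   pEE: 0.1
#'   tIMax: 1.0
#' phaseLengths: {plastic: 50000, train: 20000, test: 50000}
#' preset: inference
#' priorA: 0.33
#' ```
#'
#' Unknown keys under `params` are rejected.
#'
#' @param path path to the YAML file.
#' @return list with `params` (a [SornParams-class]), `phaseLengths`,
#'   `preset`, `priorA`, and any further top-level keys verbatim.
#' @export
readSornConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  pArgs <- cfg$params
  if (!is.null(pArgs)) {
    known <- names(formals(sornParams))
    bad <- setdiff(names(pArgs), known)
    if (length(bad))
      stop("unknown parameter keys in config: ", paste(bad, collapse = ", "))
  }
  params <- do.call(sornParams, as.list(pArgs))
  phases <- cfg$phaseLengths
  phaseLengths <- if (is.null(phases)) {
    c(plastic = 50000L, train = 20000L, test = 50000L)
  } else {
    vapply(phases[c("plastic", "train", "test")], as.integer, 0L)
  }
  out <- cfg
  out$params <- params
  out$phaseLengths <- phaseLengths
  out
}

#' Persist a recording as plain text
#'
#' Writes the spike raster in a compact sparse CSV (`step`, `letter`,
#' `activeUnits` as space-separated indices) together with a JSON sidecar
#' holding the dimensions and phase label, and reads it back.
#'
#' @param recording a [SpikeRecording-class].
#' @param path base path; `<path>.csv` and `<path>.json` are written.
#' @return `writeRecording` returns `path` invisibly; `readRecording`
#'   returns the reconstructed [SpikeRecording-class].
#' @export
writeRecording <- function(recording, path) {
  sp <- spikeRaster(recording)
  active <- vapply(seq_len(nrow(sp)), function(t)
    paste(which(sp[t, ] == 1L), collapse = " "), "")
  utils::write.csv(
    data.frame(step = seq_len(nrow(sp)),
               letter = inputLetters(recording),
               activeUnits = active),
    paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(nSteps = nrow(sp), nUnits = ncol(sp), phase = recording@phase),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  df <- utils::read.csv(paste0(path, ".csv"),
                        colClasses = c("integer", "character", "character"))
  sp <- matrix(0L, meta$nSteps, meta$nUnits)
  for (t in seq_len(nrow(df))) {
    ix <- as.integer(strsplit(df$activeUnits[t], " ")[[1]])
    if (length(ix)) sp[t, ix] <- 1L
  }
  new("SpikeRecording", spikes = sp,
      inhSpikes = matrix(0L, 0L, 0L),
      letters = df$letter, phase = meta$phase)
}

#' Persist a network state's weights and thresholds as plain text
#'
#' Writes the recurrent weights as sparse triplets (`i`, `j`, `weight`), the
#' thresholds and intrinsic-plasticity targets as CSV, and the resolved
#' parameters as JSON.
#'
#' @param state a [SornState-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportState <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  syn <- which(state@synapses, arr.ind = TRUE)
  utils::write.csv(
    data.frame(i = syn[, 1], j = syn[, 2], weight = state@wEE[syn]),
    file.path(dir, "w_ee.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(unit = seq_along(state@tE), tE = state@tE,
               hTarget = state@hTargets),
    file.path(dir, "thresholds.csv"), row.names = FALSE)
  p <- state@params
  jsonlite::write_json(
    list(nExc = p@nExc, nInh = p@nInh, pEE = p@pEE, nInput = p@nInput,
         wIn = p@wIn, etaStdp = p@etaStdp, etaIp = p@etaIp, hIp = p@hIp,
         epsIp = p@epsIp, tEMax = p@tEMax, tIMax = p@tIMax,
         pruneZeroWeights = p@pruneZeroWeights,
         structuralRate = p@structuralRate,
         structuralInit = p@structuralInit, noiseSd = p@noiseSd,
         seed = p@seed, alphabet = state@alphabet),
    file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
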