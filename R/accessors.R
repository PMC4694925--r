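#' @describeIn SornParams-class number of excitatory units.
#' @param object,x an object of the documented class.
#' @export
setGeneric("nExc", function(object) standardGeneric("nExc"))

#' @export
setMethod("nExc", "SornParams", function(object) object@nExc)

#' @export
setMethod("nExc", "SornState", function(object) object@params@nExc)

#' @describeIn SornParams-class number of inhibitory units.
#' @export
setGeneric("nInh", function(object) standardGeneric("nInh"))

#' @export
setMethod("nInh", "SornParams", function(object) object@nInh)

#' @export
setMethod("nInh", "SornState", function(object) object@params@nInh)

#' Weight matrices of a network state
#'
#' @param object a [SornState-class].
#' @param which one of `"EE"`, `"EI"`, `"IE"`, `"EU"`.
#' @param sparse return the excitatory recurrent matrix as a
#'   [Matrix::dgCMatrix-class]?
#' @return the requested weight matrix.
#' @export
setGeneric("weightMatrix",
  function(object, which = c("EE", "EI", "IE", "EU"), sparse = FALSE)
    standardGeneric("weightMatrix"))

#' @export
setMethod("weightMatrix", "SornState", function(object, which, sparse) {
  which <- match.arg(which, c("EE", "EI", "IE", "EU"))
  w <- switch(which, EE = object@wEE, EI = object@wEI,
              IE = object@wIE, EU = object@wEU)
  if (sparse && which == "EE") w <- Matrix::Matrix(w, sparse = TRUE)
  w
})

#' Synapse mask of the excitatory recurrent connectivity
#'
#' @param object a [SornState-class].
#' @return logical matrix of existing excitatory-to-excitatory synapses.
#' @export
setGeneric("synapseMask", function(object) standardGeneric("synapseMask"))

#' @export
setMethod("synapseMask", "SornState", function(object) object@synapses)

#' Excitatory thresholds
#' @param object a [SornState-class].
#' @export
setGeneric("thresholds", function(object) standardGeneric("thresholds"))

#' @export
setMethod("thresholds", "SornState", function(object) object@tE)

#' Binary spike raster of a recording
#'
#' @param object a [SpikeRecording-class].
#' @return integer matrix, steps by excitatory units.
#' @export
setGeneric("spikeRaster", function(object) standardGeneric("spikeRaster"))

#' @export
setMethod("spikeRaster", "SpikeRecording", function(object) object@spikes)

#' Letter annotation of a recording
#' @param object a [SpikeRecording-class].
#' @export
setGeneric("inputLetters", function(object) standardGeneric("inputLetters"))

#' @export
setMethod("inputLetters", "SpikeRecording", function(object) object@letters)

#' Input pools of an input map
#' @param object an [InputMap-class].
#' @export
setGeneric("inputPools", function(object) standardGeneric("inputPools"))

#' @export
setMethod("inputPools", "InputMap", function(object) object@pools)

setMethod("show", "SornParams", function(object) {
  cat("SornParams:", object@nExc, "excitatory /", object@nInh,
      "inhibitory units\n")
  cat("  pEE =", object@pEE, " nInput =", object@nInput,
      " wIn =", object@wIn, "\n")
  cat("  etaStdp =", object@etaStdp, " etaIp =", object@etaIp,
      " hIp =", object@hIp, "+/-", object@epsIp, "\n")
  cat("  tEMax =", object@tEMax, " tIMax =", object@tIMax,
      " noiseSd =", object@noiseSd, "\n")
  cat("  structuralRate =", object@structuralRate,
      " prune =", object@pruneZeroWeights, " seed =", object@seed, "\n")
  invisible(object)
})

setMethod("show", "SornState", function(object) {
  cat("SornState:", nExc(object), "E /", nInh(object), "I units;",
      sprintf("%.1f%% E->E synapses;", 100 * connectionFraction(object)),
      sum(object@x), "E units active\n")
  if (length(object@alphabet))
    cat("  input alphabet:", paste(object@alphabet, collapse = " "), "\n")
  invisible(object)
})

setMethod("show", "SpikeRecording", function(object) {
  cat("SpikeRecording [", object@phase, "]: ", nrow(object@spikes),
      " steps x ", ncol(object@spikes), " units; mean rate ",
      sprintf("%.3f", mean(object@spikes)), "\n", sep = "")
  invisible(object)
})

setMethod("show", "InputMap", function(object) {
  cat("InputMap:", length(object@alphabet), "letters x", object@nInput,
      "targets each\n")
  invisible(object)
})

setMethod("show", "ChannelParams", function(object) {
  cat("ChannelParams: theta1 =", object@theta1, " theta0 =", object@theta0,
      " prior p(A) =", object@priorA, " (", object@nUnits, "units )\n")
  invisible(object)
})

setMethod("show", "PosteriorCurve", function(object) {
  cat("PosteriorCurve over f_A in {",
      paste(format(object@fGrid), collapse = ", "), "}\n")
  cat("  neutral fraction:", format(object@neutralF),
      if (object@neutralAtBoundary) "(at boundary)" else "", "\n")
  invisible(object)
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@spikes)
  cat("TrialTensor:", d[1], "trials x", d[2], "steps x", d[3],
      "units; onset at step", object@onset, "\n")
  invisible(object)
})

setMethod("show", "LinearReadout", function(object) {
  cat("LinearReadout over classes:",
      paste(object@classes, collapse = ", "), "\n")
  invisible(object)
})
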