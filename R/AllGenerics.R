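#' @rdname EEGRecording-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname EEGRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecording-class
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname EEGRecording-class
#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @rdname EEGRecording-class
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname EEGRecording-class
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname ConnectivityMatrix-class
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))

#' Mean pairwise connectivity angle
#'
#' Arithmetic mean of the unique off-diagonal angles (upper triangle) of a
#' connectivity matrix, in degrees. Smaller means stronger overall coupling.
#'
#' @param x a \linkS4class{ConnectivityMatrix}.
#' @return numeric(1), degrees.
#' @export
setGeneric("meanAngle", function(x) standardGeneric("meanAngle"))

## -- EEGRecording methods ----------------------------------------------------

#' @rdname EEGRecording-class
#' @export
setMethod("channels", "EEGRecording", function(x) x@channels)

#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @rdname EEGRecording-class
#' @export
setMethod("signalData", "EEGRecording", function(x) x@data)

#' @rdname EEGRecording-class
#' @export
setMethod("subjectID", "EEGRecording", function(x) x@subjectID)

#' @rdname EEGRecording-class
#' @export
setMethod("groupLabel", "EEGRecording", function(x) x@group)

#' @rdname EEGRecording-class
#' @export
setMethod("duration", "EEGRecording", function(x) ncol(x@data) / x@fs)

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectID, object@group, nrow(object@data),
              ncol(object@data), object@fs, duration(object)))
  cat("channels:", paste(object@channels, collapse = " "), "\n")
})

## -- EEGSegment methods ------------------------------------------------------

#' @rdname EEGSegment-class
#' @param x an \linkS4class{EEGSegment}.
#' @export
setMethod("channels", "EEGSegment", function(x) x@channels)

#' @rdname EEGSegment-class
#' @export
setMethod("samplingRate", "EEGSegment", function(x) x@fs)

#' @rdname EEGSegment-class
#' @export
setMethod("signalData", "EEGSegment", function(x) x@data)

#' @rdname EEGSegment-class
#' @export
setMethod("subjectID", "EEGSegment", function(x) x@subjectID)

#' @rdname EEGSegment-class
#' @export
setMethod("duration", "EEGSegment", function(x) x@endS - x@startS)

setMethod("show", "EEGSegment", function(object) {
  cat(sprintf("EEGSegment %s[%d]: %.2f-%.2f s, %d channels x %d samples @ %g Hz\n",
              object@subjectID, object@segmentIndex, object@startS,
              object@endS, nrow(object@data), ncol(object@data), object@fs))
})

## -- ConnectivityMatrix methods ----------------------------------------------

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("channels", "ConnectivityMatrix", function(x) x@channels)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("angles", "ConnectivityMatrix", function(x) {
  a <- x@angles
  dimnames(a) <- list(x@channels, x@channels)
  a
})

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("subjectID", "ConnectivityMatrix", function(x) x@subjectID)

#' @rdname meanAngle
#' @export
setMethod("meanAngle", "ConnectivityMatrix", function(x)
  mean(x@angles[upper.tri(x@angles)]))

setMethod("show", "ConnectivityMatrix", function(object) {
  m <- length(object@channels)
  cat(sprintf("ConnectivityMatrix %s[%d]: %d channels, %d unique pairs, mean angle %.2f deg\n",
              object@subjectID, object@segmentIndex, m, m * (m - 1) / 2,
              meanAngle(object)))
})

## -- GaussianMixture2 methods ------------------------------------------------

setMethod("show", "GaussianMixture2", function(object) {
  cat("Two-component univariate Gaussian mixture\n")
  cat(sprintf("  weights:   %.4f  %.4f\n", object@weights[1], object@weights[2]))
  cat(sprintf("  means:     %.4f  %.4f\n", object@means[1], object@means[2]))
  cat(sprintf("  variances: %.4f  %.4f\n", object@variances[1], object@variances[2]))
  cat(sprintf("  logLik %.4f after %d iterations (converged: %s, seed %d)\n",
              object@logLik, object@iterations, object@converged, object@seed))
})

setMethod("show", "MontageSpec", function(object) {
  cat(sprintf("MontageSpec: %d electrodes (left %d, right %d, midline %d)\n",
              length(object@requiredChannels), length(object@leftSet),
              length(object@rightSet), length(object@midlineSet)))
  cat(" ", paste(object@requiredChannels, collapse = " "), "\n")
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d control + %d epilepsy subjects, %g s, fs {%s} Hz\n",
              object@nControl, object@nEpilepsy, object@durationS,
              paste(object@fs, collapse = ", ")))
  cat(sprintf("  coupling %g (control) vs %g (epilepsy), noise sd %g, seed %d\n",
              object@couplingControl, object@couplingEpilepsy,
              object@noiseSd, object@seed))
})
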