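#' @import methods
NULL

#' Multichannel scalp EEG recording
#'
#' Canonical in-memory representation of one subject's recording: a channels
#' by samples matrix of microvolt values, the electrode names in row order
#' (10-20 nomenclature, lowercase canonical), and the sampling rate.
#'
#' @slot subjectID character(1) subject identifier.
#' @slot group character(1), one of \code{"control"}, \code{"epilepsy"},
#'   \code{"unknown"}; the ground-truth diagnosis when known.
#' @slot channels character vector of electrode names, one per data row.
#' @slot fs numeric(1) sampling rate in Hz.
#' @slot data numeric matrix, channels x samples, microvolts.
#'
#' @export
setClass("EEGRecording",
  representation(
    subjectID = "character",
    group     = "character",
    channels  = "character",
    fs        = "numeric",
    data      = "matrix"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@subjectID) != 1L) msg <- c(msg, "subjectID must be length 1")
  if (!object@group %in% c("control", "epilepsy", "unknown"))
    msg <- c(msg, "group must be control, epilepsy or unknown")
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "number of channel names must equal number of data rows")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (anyDuplicated(tolower(object@channels)))
    msg <- c(msg, "channel names must be unique after case-folding")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param channels electrode names, one per row; canonicalized to lowercase.
#' @param fs sampling rate in Hz.
#' @param subjectID subject identifier.
#' @param group ground-truth label: "control", "epilepsy" or "unknown".
#' @return An \linkS4class{EEGRecording}.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 2), c("c3", "c4"), fs = 100)
#' duration(rec)
#' @export
EEGRecording <- function(data, channels, fs, subjectID = "anonymous",
                         group = c("unknown", "control", "epilepsy")) {
  group <- match.arg(group)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  new("EEGRecording", subjectID = subjectID, group = group,
      channels = tolower(as.character(channels)), fs = as.numeric(fs),
      data = data)
}

#' One fixed-length window of a recording
#'
#' @slot subjectID character(1) source subject.
#' @slot segmentIndex integer(1), zero-based index within the recording.
#' @slot startS,endS numeric(1) window bounds in seconds within the source.
#' @slot fs numeric(1) sampling rate in Hz.
#' @slot channels character electrode names.
#' @slot data channels x N matrix of the window samples.
#' @export
setClass("EEGSegment",
  representation(
    subjectID    = "character",
    segmentIndex = "integer",
    startS       = "numeric",
    endS         = "numeric",
    fs           = "numeric",
    channels     = "character",
    data         = "matrix"
  )
)

setValidity("EEGSegment", function(object) {
  msg <- character()
  if (object@segmentIndex < 0L) msg <- c(msg, "segmentIndex must be >= 0")
  if (object@endS <= object@startS) msg <- c(msg, "endS must exceed startS")
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "channel count must match data rows")
  if (length(msg)) msg else TRUE
})

#' 10-20 montage specification
#'
#' The required electrode set in canonical order, partitioned into left
#' hemisphere, right hemisphere and midline electrodes.
#'
#' @slot requiredChannels ordered electrode names.
#' @slot leftSet,rightSet,midlineSet disjoint partition of requiredChannels.
#' @export
setClass("MontageSpec",
  representation(
    requiredChannels = "character",
    leftSet          = "character",
    rightSet         = "character",
    midlineSet       = "character"
  )
)

setValidity("MontageSpec", function(object) {
  msg <- character()
  parts <- c(object@leftSet, object@rightSet, object@midlineSet)
  if (anyDuplicated(parts))
    msg <- c(msg, "hemisphere sets must be pairwise disjoint")
  if (!setequal(parts, object@requiredChannels))
    msg <- c(msg, "left/right/midline sets must partition requiredChannels")
  if (anyDuplicated(object@requiredChannels))
    msg <- c(msg, "requiredChannels must be unique")
  if (length(msg)) msg else TRUE
})

#' Undirected functional connectivity network of one segment
#'
#' Symmetric zero-diagonal matrix of pairwise angular distances (degrees)
#' between channel signals; 0 deg is maximal connectivity, 90 deg orthogonal.
#'
#' @slot channels ordered electrode names (length m).
#' @slot angles m x m symmetric matrix of angles in degrees.
#' @slot subjectID,segmentIndex provenance of the source segment.
#' @export
setClass("ConnectivityMatrix",
  representation(
    channels     = "character",
    angles       = "matrix",
    subjectID    = "character",
    segmentIndex = "integer"
  )
)

setValidity("ConnectivityMatrix", function(object) {
  msg <- character()
  a <- object@angles
  m <- length(object@channels)
  if (!all(dim(a) == c(m, m)))
    msg <- c(msg, "angles must be m x m for m channels")
  else {
    tol <- 1e-8
    if (max(abs(a - t(a))) > tol) msg <- c(msg, "angles must be symmetric")
    if (max(abs(diag(a))) > tol) msg <- c(msg, "diagonal must be zero")
    if (min(a) < -tol || max(a) > 180 + tol)
      msg <- c(msg, "angles must lie in [0, 180] degrees")
  }
  if (length(msg)) msg else TRUE
})

#' Binary and weighted graph views of a connectivity matrix
#'
#' The binary view keeps an edge where the angle is at or below the
#' binarization threshold; the weighted view carries the angle (degrees) as
#' edge length. Pairs absent from the weighted view are \code{NA}.
#'
#' @slot nodes electrode names.
#' @slot binary logical adjacency matrix (edge present).
#' @slot weights numeric matrix of edge weights in degrees; NA = no edge.
#' @slot threshold binarization threshold in degrees.
#' @export
setClass("GraphView",
  representation(
    nodes     = "character",
    binary    = "matrix",
    weights   = "matrix",
    threshold = "numeric"
  )
)

setValidity("GraphView", function(object) {
  msg <- character()
  nn <- length(object@nodes)
  if (!all(dim(object@binary) == c(nn, nn)) ||
      !all(dim(object@weights) == c(nn, nn)))
    msg <- c(msg, "binary and weights must be nn x nn")
  else {
    if (!identical(object@binary, t(object@binary)))
      msg <- c(msg, "binary adjacency must be symmetric")
    if (any(object@binary & is.na(object@weights)))
      msg <- c(msg, "binary edges must be a subset of weighted edges")
    if (any(diag(object@binary)))
      msg <- c(msg, "no self loops")
  }
  if (length(msg)) msg else TRUE
})

#' Two-component univariate Gaussian mixture fit
#'
#' @slot weights mixing proportions (sum to 1).
#' @slot means,variances component parameters on the score axis.
#' @slot logLik final log-likelihood.
#' @slot logLikTrace per-iteration log-likelihood (non-decreasing).
#' @slot iterations EM iterations used.
#' @slot converged logical(1).
#' @slot seed seed recorded for provenance.
#' @export
setClass("GaussianMixture2",
  representation(
    weights     = "numeric",
    means       = "numeric",
    variances   = "numeric",
    logLik      = "numeric",
    logLikTrace = "numeric",
    iterations  = "integer",
    converged   = "logical",
    seed        = "integer"
  )
)

setValidity("GaussianMixture2", function(object) {
  msg <- character()
  if (length(object@weights) != 2L || abs(sum(object@weights) - 1) > 1e-8 ||
      any(object@weights < 0))
    msg <- c(msg, "weights must be two non-negative values summing to 1")
  if (length(object@means) != 2L || length(object@variances) != 2L)
    msg <- c(msg, "means and variances must have length 2")
  if (any(object@variances <= 0)) msg <- c(msg, "variances must be positive")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort specification
#'
#' Study conditions for the seeded synthetic EEG generator: subject counts,
#' sampling rates (cycled across subjects), duration, group coupling
#' coefficients and noise level.
#'
#' @slot nControl,nEpilepsy subject counts per group.
#' @slot fs sampling rates in Hz, recycled over subjects within each group.
#' @slot durationS recording duration in seconds.
#' @slot couplingControl,couplingEpilepsy shared-source mixing coefficient in
#'   [0, 1] per group; larger coupling means smaller expected pairwise angles.
#' @slot noiseSd standard deviation of per-channel white noise.
#' @slot seed master seed; all per-subject seeds derive from it.
#' @export
setClass("CohortSpec",
  representation(
    nControl         = "integer",
    nEpilepsy        = "integer",
    fs               = "numeric",
    durationS        = "numeric",
    couplingControl  = "numeric",
    couplingEpilepsy = "numeric",
    noiseSd          = "numeric",
    seed             = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nControl < 0L || object@nEpilepsy < 0L)
    msg <- c(msg, "subject counts must be >= 0")
  if (any(c(object@couplingControl, object@couplingEpilepsy) < 0) ||
      any(c(object@couplingControl, object@couplingEpilepsy) > 1))
    msg <- c(msg, "coupling coefficients must lie in [0, 1]")
  if (any(object@fs <= 0)) msg <- c(msg, "fs must be positive")
  if (any(object@durationS <= 0)) msg <- c(msg, "durationS must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})
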