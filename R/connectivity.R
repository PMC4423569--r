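#' Angular distance between two channel signals
#'
#' The connectivity strength between two equal-length signals is the
#' arc-cosine of their normalized inner product (a modified cosine
#' similarity): 0 deg means the signals point in the same direction (maximal
#' connectivity), 90 deg means orthogonal signals (no linear association).
#' Under the default convention anti-parallel signals give 180 deg; the
#' \code{"literal"} convention returns the complementary angle
#' \code{180 - acos(sim)}, and \code{absolute = TRUE} folds angles into
#' [0, 90] by taking \code{acos(|sim|)}.
#'
#' The measure is invariant to positive rescaling of either signal, so
#' recordings at different sampling rates and amplifier gains are directly
#' comparable.
#'
#' @param x,y numeric vectors of equal, nonzero length.
#' @param convention \code{"distance"} (default, \code{acos(sim)}) or
#'   \code{"literal"} (\code{180 - acos(sim)}).
#' @param center subtract each signal's mean first (default FALSE: the raw
#'   inner product is used).
#' @param absolute fold into [0, 90] via \code{acos(|sim|)} (default FALSE).
#' @param degrees return degrees (default) or radians.
#' @return numeric(1) angle.
#' @examples
#' pairwiseAngle(sin(1:100), 2.5 * sin(1:100))  # 0
#' pairwiseAngle(c(1, 0), c(0, 1))              # 90
#' @export
pairwiseAngle <- function(x, y, convention = c("distance", "literal"),
                          center = FALSE, absolute = FALSE, degrees = TRUE) {
  convention <- match.arg(convention)
  if (length(x) != length(y))
    stop("contract error: signals must have equal length (", length(x),
         " vs ", length(y), ")")
  if (!length(x)) stop("contract error: empty signals")
  if (center) { x <- x - mean(x); y <- y - mean(y) }
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stop("undefined angle: zero-norm (flat) channel signal")
  sim <- sum(x * y) / (nx * ny)
  sim <- min(1, max(-1, sim))
  if (absolute) sim <- abs(sim)
  theta <- acos(sim)
  if (convention == "literal") theta <- pi - theta
  if (degrees) theta * 180 / pi else theta
}

#' Build the functional connectivity network of a segment
#'
#' Computes the symmetric, zero-diagonal matrix of pairwise angular distances
#' (\code{\link{pairwiseAngle}}) over all channel pairs of a segment:
#' C(m, 2) unique values for m channels (171 for the 19-electrode montage).
#'
#' @param seg an \linkS4class{EEGSegment} (or \linkS4class{EEGRecording})
#'   with at least two channels and finite values.
#' @inheritParams pairwiseAngle
#' @return A \linkS4class{ConnectivityMatrix} in degrees.
#' @export
buildFCN <- function(seg, convention = c("distance", "literal"),
                     center = FALSE, absolute = FALSE) {
  convention <- match.arg(convention)
  x <- signalData(seg)
  if (nrow(x) < 2) stop("contract error: need at least 2 channels")
  if (!all(is.finite(x))) stop("contract error: non-finite sample values")
  if (center) x <- x - rowMeans(x)
  g <- tcrossprod(x)
  nrm <- sqrt(diag(g))
  flat <- which(nrm == 0)
  if (length(flat))
    stop("undefined angle: zero-norm (flat) channel signal: ",
         paste(channels(seg)[flat], collapse = ", "))
  sim <- g / outer(nrm, nrm)
  sim <- pmax(pmin(sim, 1), -1)
  if (absolute) sim <- abs(sim)
  theta <- acos(sim) * 180 / pi
  if (convention == "literal") theta <- 180 - theta
  diag(theta) <- 0
  theta <- (theta + t(theta)) / 2  # exact symmetry against fp noise
  segIdx <- if (is(seg, "EEGSegment")) seg@segmentIndex else NA_integer_
  new("ConnectivityMatrix", channels = channels(seg), angles = theta,
      subjectID = subjectID(seg), segmentIndex = segIdx)
}

#' Entrywise mean of connectivity matrices
#'
#' @param ms nonempty list of \linkS4class{ConnectivityMatrix} with identical
#'   channel orderings.
#' @return A \linkS4class{ConnectivityMatrix}: the entrywise arithmetic mean.
#' @export
meanFCN <- function(ms) {
  if (!length(ms)) stop("contract error: empty list of matrices")
  ch <- ms[[1]]@channels
  for (m in ms)
    if (!identical(m@channels, ch))
      stop("contract error: mixed channel orderings across matrices")
  avg <- Reduce(`+`, lapply(ms, function(m) m@angles)) / length(ms)
  new("ConnectivityMatrix", channels = ch, angles = avg,
      subjectID = "group-mean", segmentIndex = NA_integer_)
}

#' Canonical electrode-pair labels
#'
#' Row-major upper-triangle ordering of the channel list: for channels
#' (a, b, c) the pairs are a-b, a-c, b-c. This ordering is fixed across all
#' segments so edge vectors are comparable position-by-position.
#'
#' @param ch character vector of channel names.
#' @return character vector of C(m, 2) pair labels "chi-chj", i < j.
#' @export
pairLabels <- function(ch) {
  m <- length(ch)
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  paste0(ch[idx[, "row"]], "-", ch[idx[, "col"]])
}

#' Flatten a connectivity matrix to its canonical edge vector
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @return data.frame with columns \code{pair} (canonical label, see
#'   \code{\link{pairLabels}}) and \code{angle} (degrees); the channel order
#'   is kept in \code{attr(, "channels")} so the matrix can be rebuilt with
#'   \code{\link{edgeVectorToMatrix}}.
#' @export
vectorizeUpper <- function(m) {
  stopifnot(is(m, "ConnectivityMatrix"))
  nm <- length(m@channels)
  idx <- which(upper.tri(m@angles), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  out <- data.frame(pair = pairLabels(m@channels),
                    angle = m@angles[idx],
                    stringsAsFactors = FALSE)
  attr(out, "channels") <- m@channels
  out
}

#' Rebuild a connectivity matrix from an edge vector
#'
#' Inverse of \code{\link{vectorizeUpper}}.
#'
#' @param ev data.frame as returned by \code{\link{vectorizeUpper}} (or any
#'   with \code{angle} in canonical order).
#' @param channels channel names; defaults to \code{attr(ev, "channels")}.
#' @return A \linkS4class{ConnectivityMatrix}.
#' @export
edgeVectorToMatrix <- function(ev, channels = attr(ev, "channels")) {
  if (is.null(channels)) stop("channel names required")
  m <- length(channels)
  if (nrow(ev) != m * (m - 1) / 2)
    stop("contract error: edge vector length does not match channel count")
  a <- matrix(0, m, m)
  idx <- which(upper.tri(a), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  a[idx] <- ev$angle
  a <- a + t(a)
  new("ConnectivityMatrix", channels = channels, angles = a,
      subjectID = "rebuilt", segmentIndex = NA_integer_)
}

#' Serialize a connectivity matrix as delimited text
#'
#' Square matrix with a channel-name header row and column.
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeConnectivityMatrix <- function(m, path) {
  a <- angles(m)
  utils::write.table(a, path, sep = "\t", quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}
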