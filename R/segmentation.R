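#' Split a recording into fixed-length overlapping segments
#'
#' Applies a moving window of \code{windowS} seconds advancing by
#' \code{windowS - overlapS}; trailing samples that do not fill a full window
#' are discarded. A recording shorter than one window yields an empty list
#' with a warning. With the defaults (9 s window, 4.5 s overlap) a 90 s
#' recording yields 19 segments.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param windowS window length in seconds (default 9).
#' @param overlapS overlap between consecutive windows in seconds
#'   (default 4.5); must satisfy \code{0 <= overlapS < windowS}.
#' @return list of \linkS4class{EEGSegment}, ordered by start time.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(2 * 2000), 2), c("c3", "c4"), fs = 100)
#' length(segmentRecording(rec))  # floor((20 - 9)/4.5) + 1 = 3
#' @export
segmentRecording <- function(rec, windowS = 9, overlapS = 4.5) {
  stopifnot(is(rec, "EEGRecording"))
  if (overlapS >= windowS || overlapS < 0)
    stop("configuration error: need 0 <= overlapS < windowS (got overlap ",
         overlapS, ", window ", windowS, ")")
  fs <- rec@fs
  n <- ncol(rec@data)
  N <- round(windowS * fs)
  step <- round((windowS - overlapS) * fs)
  if (n < N) {
    warning(sprintf("recording '%s' (%.3g s) shorter than the %g s window: 0 segments",
                    rec@subjectID, n / fs, windowS))
    return(list())
  }
  starts <- seq.int(0L, n - N, by = step)
  lapply(seq_along(starts), function(i) {
    s0 <- starts[i]
    new("EEGSegment",
        subjectID = rec@subjectID,
        segmentIndex = i - 1L,
        startS = s0 / fs,
        endS = s0 / fs + windowS,
        fs = fs,
        channels = rec@channels,
        data = rec@data[, (s0 + 1):(s0 + N), drop = FALSE])
  })
}

#' Tabulate a segment list
#'
#' @param segments list of \linkS4class{EEGSegment} (possibly from several
#'   recordings).
#' @return data.frame with subject_id, segment_index, start_s, end_s columns,
#'   suitable for export as a delimited inventory.
#' @export
segmentInventory <- function(segments) {
  data.frame(
    subject_id    = vapply(segments, function(s) s@subjectID, ""),
    segment_index = vapply(segments, function(s) s@segmentIndex, 0L),
    start_s       = vapply(segments, function(s) s@startS, 0),
    end_s         = vapply(segments, function(s) s@endS, 0),
    stringsAsFactors = FALSE)
}
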