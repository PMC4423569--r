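#' Synthetic cohort specification
#'
#' Study conditions for the synthetic EEG generator. The defaults mirror the
#' reference cohort structure: 7 control-like and 11 epilepsy-like subjects,
#' sampling rates cycling over 200/500/512 Hz, 90 s recordings, and group
#' identity encoded purely through the shared-source coupling coefficient
#' (0.8 for controls, 0.3 for epilepsy), since the angular metric is
#' amplitude-invariant. Larger coupling yields smaller expected pairwise
#' angles (stronger apparent connectivity).
#'
#' @param nControl,nEpilepsy subject counts (defaults 7 and 11).
#' @param fs sampling rates in Hz, recycled over subjects (default
#'   c(200, 500, 512)).
#' @param durationS recording duration in seconds (default 90).
#' @param couplingControl,couplingEpilepsy shared-source mixing weights in
#'   [0, 1] (defaults 0.8 and 0.3).
#' @param noiseSd white-noise standard deviation per channel (default 1; the
#'   latent sources have unit variance).
#' @param seed master seed for bit-reproducible generation.
#' @return A \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nControl = 7L, nEpilepsy = 11L, fs = c(200, 500, 512),
                       durationS = 90, couplingControl = 0.8,
                       couplingEpilepsy = 0.3, noiseSd = 1, seed = 1L) {
  new("CohortSpec", nControl = as.integer(nControl),
      nEpilepsy = as.integer(nEpilepsy), fs = as.numeric(fs),
      durationS = as.numeric(durationS),
      couplingControl = couplingControl,
      couplingEpilepsy = couplingEpilepsy,
      noiseSd = noiseSd, seed = as.integer(seed))
}

# Band-limited (1-30 Hz) unit-variance noise: white noise through a 4th-order
# Butterworth band-pass, forward-backward filtered for zero phase. Band-limited
# sources avoid the accidental exact orthogonality of pure sinusoids.
bandlimitedNoise <- function(n, fs, band = c(1, 30)) {
  ny <- fs / 2
  bf <- signal::butter(4, pmin(band / ny, 0.99), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate band-limited source")
  x / s
}

#' Generate one synthetic multichannel recording
#'
#' Each channel is \code{a * sCommon + (1 - a) * sRegion + noise}, where
#' \code{sCommon} is one shared broadband (1-30 Hz band-limited) latent
#' signal, \code{sRegion} is a latent specific to the channel's region (left
#' hemisphere, right hemisphere, or midline), the noise is white with the
#' spec's standard deviation, and \code{a} is the group's coupling
#' coefficient. Channels follow the default 19-electrode montage order.
#'
#' @param group \code{"control"} or \code{"epilepsy"}.
#' @param spec a \linkS4class{CohortSpec}.
#' @param subjectSeed integer seed for this subject.
#' @param subjectID identifier for the returned recording.
#' @param fs sampling rate in Hz; defaults to the first rate in the spec.
#' @return An \linkS4class{EEGRecording} with 19 channels.
#' @export
generateRecording <- function(group, spec = cohortSpec(), subjectSeed = 1L,
                              subjectID = NULL, fs = spec@fs[1]) {
  if (!group %in% c("control", "epilepsy"))
    stop("contract error: group must be 'control' or 'epilepsy'")
  a <- if (group == "control") spec@couplingControl else spec@couplingEpilepsy
  montage <- defaultMontage()
  ch <- montage@requiredChannels
  region <- ifelse(ch %in% montage@leftSet, "L",
                   ifelse(ch %in% montage@rightSet, "R", "Z"))
  n <- round(spec@durationS * fs)
  set.seed(as.integer(subjectSeed))
  sCommon <- bandlimitedNoise(n, fs)
  sRegion <- list(L = bandlimitedNoise(n, fs),
                  R = bandlimitedNoise(n, fs),
                  Z = bandlimitedNoise(n, fs))
  data <- matrix(0, nrow = length(ch), ncol = n)
  for (i in seq_along(ch)) {
    eps <- if (spec@noiseSd > 0) stats::rnorm(n, 0, spec@noiseSd) else 0
    data[i, ] <- a * sCommon + (1 - a) * sRegion[[region[i]]] + eps
  }
  if (is.null(subjectID))
    subjectID <- paste0("synthetic-", group)
  EEGRecording(data, channels = ch, fs = fs, subjectID = subjectID,
               group = group)
}

#' Generate a full synthetic cohort
#'
#' Per-subject seeds are drawn deterministically from the master seed, so
#' the whole cohort is bit-reproducible. Sampling rates cycle over
#' \code{spec@fs} within each group.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @return list with \code{recordings} (list of \linkS4class{EEGRecording})
#'   and \code{truth} (data.frame: subject_id, group, fs, duration_s).
#' @examples
#' cohort <- generateCohort(cohortSpec(nControl = 1, nEpilepsy = 1,
#'                                     durationS = 10))
#' cohort$truth
#' @export
generateCohort <- function(spec = cohortSpec()) {
  nTot <- spec@nControl + spec@nEpilepsy
  if (nTot < 1) stop("contract error: need at least one subject")
  set.seed(spec@seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nTot)
  groups <- c(rep("control", spec@nControl), rep("epilepsy", spec@nEpilepsy))
  ids <- c(sprintf("PC%02d", seq_len(spec@nControl)),
           sprintf("PE%02d", seq_len(spec@nEpilepsy)))
  fsBy <- c(rep_len(spec@fs, spec@nControl), rep_len(spec@fs, spec@nEpilepsy))
  recordings <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    recordings[[i]] <- generateRecording(groups[i], spec,
                                         subjectSeed = seeds[i],
                                         subjectID = ids[i], fs = fsBy[i])
  }
  names(recordings) <- ids
  truth <- data.frame(subject_id = ids, group = groups, fs = fsBy,
                      duration_s = spec@durationS,
                      stringsAsFactors = FALSE)
  list(recordings = recordings, truth = truth)
}

#' Write a cohort to disk
#'
#' One file per subject (csv via \code{\link{writeRecordingCSV}} or EDF via
#' \code{\link{writeEDF}}) plus a \code{truth.tsv} table.
#'
#' @param cohort list from \code{\link{generateCohort}}.
#' @param dir output directory (created if needed).
#' @param format \code{"csv"} or \code{"edf"}.
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    path <- file.path(dir, paste0(rec@subjectID, ".", format))
    if (format == "csv") writeRecordingCSV(rec, path) else writeEDF(rec, path)
  }
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
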