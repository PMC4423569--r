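#' Default 19-electrode 10-20 montage
#'
#' The standard 19-channel 10-20 referential montage. Odd-numbered electrodes
#' form the left hemisphere set, even-numbered the right, and the z-suffixed
#' electrodes (fz, cz, pz) the midline, following 10-20 convention.
#'
#' @return A \linkS4class{MontageSpec} with 19 electrodes.
#' @examples
#' defaultMontage()
#' @export
defaultMontage <- function() {
  req <- c("fp1", "fp2", "f7", "f3", "fz", "f4", "f8", "t3", "c3", "cz",
           "c4", "t4", "t5", "p3", "pz", "p4", "t6", "o1", "o2")
  new("MontageSpec",
      requiredChannels = req,
      leftSet    = c("fp1", "f7", "f3", "t3", "c3", "t5", "p3", "o1"),
      rightSet   = c("fp2", "f4", "f8", "c4", "t4", "p4", "t6", "o2"),
      midlineSet = c("fz", "cz", "pz"))
}

#' Read a multichannel EEG recording
#'
#' Reads EDF (16-bit, one signal per electrode) or delimited text (one column
#' per channel, optional leading \code{"# fs=<Hz>"} comment line, then a
#' header row of channel names) into an \linkS4class{EEGRecording}.
#'
#' @param path path to the file.
#' @param format \code{"edf"} or \code{"csv"}; guessed from the extension
#'   when missing.
#' @param fsOverride sampling rate in Hz; required for csv files without an
#'   \code{fs} comment line, ignored for EDF.
#' @param subjectID subject identifier; defaults to the file base name.
#' @param group optional ground-truth label.
#' @return An \linkS4class{EEGRecording} with channels in file order.
#' @export
readRecording <- function(path, format = c("auto", "edf", "csv"),
                          fsOverride = NULL, subjectID = NULL,
                          group = "unknown") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read recording: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "edf") "edf" else "csv"
  }
  if (is.null(subjectID))
    subjectID <- tools::file_path_sans_ext(basename(path))
  if (format == "edf") readEDF(path, subjectID = subjectID, group = group)
  else readRecordingCSV(path, fsOverride = fsOverride,
                        subjectID = subjectID, group = group)
}

#' @rdname readRecording
#' @export
readRecordingCSV <- function(path, fsOverride = NULL, subjectID = "anonymous",
                             group = "unknown") {
  lines <- readLines(path)
  if (!length(lines)) stop("empty recording file: ", path)
  fs <- fsOverride
  if (grepl("^#", lines[1])) {
    m <- regmatches(lines[1], regexec("fs\\s*=\\s*([0-9.]+)", lines[1]))[[1]]
    if (length(m) == 2) fs <- as.numeric(m[2])
    lines <- lines[-1]
  }
  if (is.null(fs) || !is.finite(fs))
    stop("sampling rate missing: csv input needs an '# fs=<Hz>' line or fsOverride")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  header <- trimws(header)
  body <- lines[-1]
  body <- body[nzchar(body)]
  cells <- strsplit(body, ",", fixed = TRUE)
  nch <- length(header)
  vals <- matrix(NA_real_, nrow = length(body), ncol = nch)
  for (r in seq_along(cells)) {
    row <- trimws(cells[[r]])
    if (length(row) != nch)
      stop(sprintf("parse error at data row %d: expected %d cells, found %d",
                   r, nch, length(row)))
    v <- suppressWarnings(as.numeric(row))
    bad <- which(is.na(v) & !(row %in% c("NA")))
    if (length(bad))
      stop(sprintf("parse error: non-numeric cell at data row %d, column %d ('%s')",
                   r, bad[1], row[bad[1]]))
    vals[r, ] <- v
  }
  EEGRecording(t(vals), channels = header, fs = fs,
               subjectID = subjectID, group = group)
}

#' Write a recording as delimited text
#'
#' Emits the format \code{\link{readRecordingCSV}} reads: an \code{# fs=} line,
#' a channel-name header, then one row per sample.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRecordingCSV <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g", rec@fs), con)
  writeLines(paste(rec@channels, collapse = ","), con)
  rows <- apply(t(rec@data), 1L, function(r)
    paste(sprintf("%.10g", r), collapse = ","))
  writeLines(rows, con)
  invisible(path)
}

## -- EDF (European Data Format, 16-bit) --------------------------------------

edfPad <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Read an EDF file
#'
#' Minimal EDF reader: fixed 256-byte header plus per-signal headers, 16-bit
#' little-endian samples, rescaled to physical units via the declared
#' physical/digital ranges. All signals must share one sampling rate.
#'
#' @param path path to the .edf file.
#' @param subjectID,group metadata for the returned recording.
#' @return An \linkS4class{EEGRecording}.
#' @export
readEDF <- function(path, subjectID = "anonymous", group = "unknown") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) stop("unsupported EDF version: ", version)
  rd(80); rd(80); rd(8); rd(8)  # patient, recording, start date, start time
  rd(8)                          # header byte count
  rd(44)                         # reserved
  nRecords <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)  # transducer
  for (i in seq_len(ns)) rd(8)   # physical dimension
  physMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)  # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)  # reserved
  if (length(unique(spr / recDur)) != 1L)
    stop("EDF signals with heterogeneous sampling rates are not supported")
  fs <- spr[1] / recDur
  data <- matrix(0, nrow = ns, ncol = nRecords * spr[1])
  for (r in seq_len(nRecords)) {
    for (s in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[s], size = 2L,
                     endian = "little", signed = TRUE)
      phys <- physMin[s] + (dig - digMin[s]) *
        (physMax[s] - physMin[s]) / (digMax[s] - digMin[s])
      data[s, ((r - 1) * spr[s] + 1):(r * spr[s])] <- phys
    }
  }
  EEGRecording(data, channels = labels, fs = fs,
               subjectID = subjectID, group = group)
}

#' Write a recording to EDF
#'
#' Writes 16-bit EDF with one data record per second; the duration is
#' truncated to whole seconds. Physical ranges are taken per signal from the
#' data, so round-trip precision is about range/65535.
#'
#' @param rec an \linkS4class{EEGRecording} with integer sampling rate.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- rec@fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  ns <- nrow(rec@data)
  nRecords <- floor(ncol(rec@data) / fs)
  if (nRecords < 1) stop("recording shorter than one EDF data record (1 s)")
  x <- rec@data[, seq_len(nRecords * fs), drop = FALSE]
  physMin <- apply(x, 1L, min)
  physMax <- apply(x, 1L, max)
  flat <- physMax - physMin < .Machine$double.eps
  physMax[flat] <- physMin[flat] + 1
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(edfPad(x, width), con, eos = NULL)
  wr("0", 8)
  wr(rec@subjectID, 80)
  wr("epiFCN export", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 + 256 * ns, 8)
  wr("", 44)
  wr(nRecords, 8)
  wr("1", 8)
  wr(ns, 4)
  for (ch in rec@channels) wr(ch, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in physMin) wr(sprintf("%.8g", v), 8)
  for (v in physMax) wr(sprintf("%.8g", v), 8)
  for (i in seq_len(ns)) wr(digMin, 8)
  for (i in seq_len(ns)) wr(digMax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(nRecords)) {
    for (s in seq_len(ns)) {
      seg <- x[s, ((r - 1) * fs + 1):(r * fs)]
      dig <- round(digMin + (seg - physMin[s]) *
                     (digMax - digMin) / (physMax[s] - physMin[s]))
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

## -- montage conformance -----------------------------------------------------

#' Conform a recording to a montage
#'
#' Reorders channels to the montage's canonical order (case-insensitive
#' matching); extra channels are dropped with a warning and any missing
#' required channel is an error.
#'
#' @param rec an \linkS4class{EEGRecording}.
#' @param spec a \linkS4class{MontageSpec}; default \code{\link{defaultMontage}()}.
#' @return An \linkS4class{EEGRecording} whose channels equal
#'   \code{spec@requiredChannels} in order. Idempotent.
#' @export
conformMontage <- function(rec, spec = defaultMontage()) {
  stopifnot(is(rec, "EEGRecording"), is(spec, "MontageSpec"))
  have <- tolower(rec@channels)
  want <- tolower(spec@requiredChannels)
  missing <- setdiff(want, have)
  if (length(missing))
    stop("montage error: missing required channel(s): ",
         paste(missing, collapse = ", "))
  extra <- setdiff(have, want)
  if (length(extra))
    warning("dropping channel(s) not in montage: ",
            paste(extra, collapse = ", "))
  idx <- match(want, have)
  EEGRecording(rec@data[idx, , drop = FALSE], channels = want, fs = rec@fs,
               subjectID = rec@subjectID, group = rec@group)
}

#' Demographics of the reference study cohort
#'
#' Per-subject demographics of the 18-subject pediatric cohort (7 control,
#' 11 epilepsy) the method was developed on: age, sex, diagnosis, sampling
#' rate and artifact-free segment count per subject.
#'
#' @return data.frame with columns subject_id, group, age, sex, diagnosis,
#'   sampling_rate_hz, n_segments.
#' @export
cohortDemographics <- function() {
  path <- system.file("extdata", "cohort_demographics.tsv", package = "epiFCN",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
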