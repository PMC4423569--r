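# Small deterministic fixtures built in code.

toyRecording <- function(nChannels = 4, seconds = 20, fs = 100, seed = 7,
                         subjectID = "toy", group = "unknown") {
  set.seed(seed)
  EEGRecording(matrix(rnorm(nChannels * seconds * fs), nrow = nChannels),
               channels = paste0("ch", seq_len(nChannels)),
               fs = fs, subjectID = subjectID, group = group)
}

montageRecording <- function(seconds = 10, fs = 100, seed = 11,
                             shuffle = FALSE, extra = character(),
                             drop = character()) {
  set.seed(seed)
  ch <- c(defaultMontage()@requiredChannels, extra)
  ch <- setdiff(ch, drop)
  if (shuffle) ch <- sample(ch)
  EEGRecording(matrix(rnorm(length(ch) * seconds * fs), nrow = length(ch)),
               channels = ch, fs = fs, subjectID = "montage-toy")
}

# ConnectivityMatrix with every off-diagonal angle equal.
uniformConnectivity <- function(m, angle, channels = paste0("ch", seq_len(m))) {
  a <- matrix(angle, m, m)
  diag(a) <- 0
  new("ConnectivityMatrix", channels = channels, angles = a,
      subjectID = "uniform", segmentIndex = 0L)
}

# GraphView for a hand-specified edge list (weights in degrees).
toyGraph <- function(nNodes, edges, threshold = 45) {
  w <- matrix(NA_real_, nNodes, nNodes)
  for (e in edges) {
    w[e[[1]], e[[2]]] <- e[[3]]
    w[e[[2]], e[[1]]] <- e[[3]]
  }
  graphView(paste0("n", seq_len(nNodes)), w, threshold = threshold)
}

# Table 5 analogue embedded for decision-layer tests: printed per-subject
# epileptic segment counts (e_s), totals (d_s) and probabilities (%).
referenceSubjectTable <- function() {
  data.frame(
    subject_id = c(sprintf("PC%02d", 1:7), sprintf("PE%02d", 1:11)),
    group = c(rep("control", 7), rep("epilepsy", 11)),
    e_s = c(0, 0, 0, 2, 0, 0, 1,
            12, 67, 10, 12, 21, 66, 30, 23, 25, 5, 3),
    d_s = c(11, 20, 14, 18, 3, 20, 5,
            14, 67, 39, 18, 30, 77, 40, 25, 25, 6, 13),
    printed_pct = c(0, 0, 0, 11, 0, 0, 20,
                    86, 100, 25, 66, 70, 86, 75, 92, 100, 83, 23),
    stringsAsFactors = FALSE)
}
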