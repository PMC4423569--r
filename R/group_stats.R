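#' Pooled two-sample t-test between two edge-value samples
#'
#' Two-sided Student t-test with pooled variance over two sets of edge
#' values (for example the upper triangles of two group-mean connectivity
#' networks); degrees of freedom are n1 + n2 - 2, so two 171-edge vectors
#' give df = 340.
#'
#' @param edgesA,edgesB numeric vectors of edge angles (degrees), or
#'   data.frames from \code{\link{vectorizeUpper}}.
#' @return named list with \code{t}, \code{df}, \code{p}, and the group
#'   means.
#' @export
groupMeanTest <- function(edgesA, edgesB) {
  if (is.data.frame(edgesA)) edgesA <- edgesA$angle
  if (is.data.frame(edgesB)) edgesB <- edgesB$angle
  if (length(edgesA) < 2 || length(edgesB) < 2)
    stop("contract error: each sample needs at least 2 edge values")
  tt <- stats::t.test(edgesA, edgesB, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, meanA = mean(edgesA), meanB = mean(edgesB))
}

#' Edgewise two-sample t-tests across groups
#'
#' One pooled two-sample t-test per canonical electrode pair, comparing the
#' per-segment angles of the two groups. Following the method's operational
#' multiple-comparison rule, an edge is significant when its raw p-value is
#' below the fixed adjusted threshold (1e-5 by default); classical
#' Bonferroni (alpha divided by the number of testable pairs) is available
#' via \code{bonferroni = TRUE}. A pair with zero variance in both groups is
#' untestable: it is reported with NA statistics, excluded from the
#' significance mask, and counted in a warning.
#'
#' @param edgesA,edgesB segments x pairs numeric matrices of angles, one row
#'   per segment, columns in canonical pair order (see
#'   \code{\link{edgeMatrix}}); at least two rows each.
#' @param alphaAdj significance threshold applied to raw p-values
#'   (default 1e-5).
#' @param bonferroni when TRUE, use \code{alphaAdj / n_testable} instead of
#'   the fixed threshold.
#' @return data.frame with one row per pair: pair, t, p, significant,
#'   testable.
#' @export
edgewiseTests <- function(edgesA, edgesB, alphaAdj = 1e-5,
                          bonferroni = FALSE) {
  edgesA <- as.matrix(edgesA); edgesB <- as.matrix(edgesB)
  if (nrow(edgesA) < 2 || nrow(edgesB) < 2)
    stop("contract error: need at least 2 segments per group")
  if (ncol(edgesA) != ncol(edgesB))
    stop("contract error: pair counts differ between groups")
  pairs <- colnames(edgesA)
  if (is.null(pairs)) pairs <- paste0("pair", seq_len(ncol(edgesA)))
  np <- ncol(edgesA)
  t <- p <- rep(NA_real_, np)
  testable <- rep(TRUE, np)
  for (j in seq_len(np)) {
    a <- edgesA[, j]; b <- edgesB[, j]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      testable[j] <- FALSE
      next
    }
    tt <- stats::t.test(a, b, var.equal = TRUE)
    t[j] <- unname(tt$statistic)
    p[j] <- tt$p.value
  }
  if (any(!testable))
    warning(sum(!testable), " pair(s) untestable (zero within-group variance)")
  thr <- if (bonferroni) alphaAdj / sum(testable) else alphaAdj
  data.frame(pair = pairs, t = t, p = p,
             significant = !is.na(p) & p < thr,
             testable = testable,
             stringsAsFactors = FALSE)
}

#' Stack edge vectors of many segments into a matrix
#'
#' @param fcns list of \linkS4class{ConnectivityMatrix} with identical
#'   channel orderings.
#' @return segments x pairs matrix with canonical pair labels as column
#'   names.
#' @export
edgeMatrix <- function(fcns) {
  if (!length(fcns)) stop("contract error: empty list")
  evs <- lapply(fcns, vectorizeUpper)
  out <- do.call(rbind, lapply(evs, function(e) e$angle))
  colnames(out) <- evs[[1]]$pair
  out
}

#' Export the edgewise significance mask as a 0/1 matrix
#'
#' @param tests data.frame from \code{\link{edgewiseTests}}.
#' @param channels channel names defining the canonical pair order.
#' @return square 0/1 integer matrix (untestable pairs are 0) with channel
#'   dimnames.
#' @export
significanceMask <- function(tests, channels) {
  m <- length(channels)
  if (nrow(tests) != m * (m - 1) / 2)
    stop("contract error: test count does not match channel count")
  mask <- matrix(0L, m, m, dimnames = list(channels, channels))
  idx <- which(upper.tri(mask), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  mask[idx] <- as.integer(tests$significant)
  mask + t(mask)
}

#' Hemispheric strong-connection counts
#'
#' Counts edges whose angle is at or below the threshold (45 deg by default,
#' the mid-point of connectivity strength), split by hemisphere: edges with
#' both endpoints in the right set, both in the left set, and edges bridging
#' the two hemispheres. Edges touching midline electrodes (fz, cz, pz) are
#' excluded from all three counts by default; \code{midline = "inter"}
#' assigns midline-touching edges to the inter-hemisphere count instead.
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @param spec a \linkS4class{MontageSpec} covering the matrix channels.
#' @param threshold degrees (default 45).
#' @param midline \code{"exclude"} (default) or \code{"inter"}.
#' @return named numeric: right, left, inter.
#' @export
hemisphereDensity <- function(m, spec = defaultMontage(), threshold = 45,
                              midline = c("exclude", "inter")) {
  midline <- match.arg(midline)
  ch <- m@channels
  side <- ifelse(ch %in% spec@leftSet, "L",
                 ifelse(ch %in% spec@rightSet, "R",
                        ifelse(ch %in% spec@midlineSet, "Z", NA)))
  if (anyNA(side))
    stop("contract error: channel(s) absent from montage partition: ",
         paste(ch[is.na(side)], collapse = ", "))
  strong <- m@angles <= threshold
  diag(strong) <- FALSE
  idx <- which(upper.tri(strong) & strong, arr.ind = TRUE)
  s1 <- side[idx[, 1]]; s2 <- side[idx[, 2]]
  right <- sum(s1 == "R" & s2 == "R")
  left  <- sum(s1 == "L" & s2 == "L")
  inter <- sum((s1 == "L" & s2 == "R") | (s1 == "R" & s2 == "L"))
  if (midline == "inter")
    inter <- inter + sum(s1 == "Z" | s2 == "Z")
  c(right = right, left = left, inter = inter)
}

#' Per-subject hemispheric density summary
#'
#' Mean and standard deviation of the strong-edge counts across a subject's
#' segments, per hemisphere category.
#'
#' @param fcns list of \linkS4class{ConnectivityMatrix} for one subject's
#'   segments.
#' @inheritParams hemisphereDensity
#' @return data.frame with one row per category: category, mean, sd.
#' @export
hemisphereDensitySummary <- function(fcns, spec = defaultMontage(),
                                     threshold = 45,
                                     midline = c("exclude", "inter")) {
  midline <- match.arg(midline)
  counts <- t(vapply(fcns, hemisphereDensity, numeric(3), spec = spec,
                     threshold = threshold, midline = midline))
  data.frame(category = colnames(counts),
             mean = colMeans(counts),
             sd = apply(counts, 2L, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}
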