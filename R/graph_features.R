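#' Map a connectivity matrix to graph views
#'
#' Produces the two graph representations the feature set works on: a binary
#' graph keeping an edge where the angle is less than or equal to the
#' threshold (45 deg by default, the mid-point of connectivity strength), and
#' the complete weighted graph whose edge lengths are the angles in degrees.
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @param threshold binarization threshold in degrees, in (0, 180].
#' @return A \linkS4class{GraphView}.
#' @export
toGraph <- function(m, threshold = 45) {
  stopifnot(is(m, "ConnectivityMatrix"))
  if (threshold <= 0 || threshold > 180)
    stop("threshold must lie in (0, 180] degrees")
  w <- m@angles
  diag(w) <- NA_real_
  graphView(m@channels, w, threshold = threshold)
}

#' Construct a GraphView from a weight matrix
#'
#' @param nodes node names.
#' @param weights symmetric matrix of edge weights in degrees; \code{NA}
#'   marks an absent pair (the diagonal is always ignored).
#' @param threshold binarization threshold in degrees.
#' @return A \linkS4class{GraphView}; binary edges are the weighted pairs at
#'   or below the threshold.
#' @export
graphView <- function(nodes, weights, threshold = 45) {
  weights <- as.matrix(weights)
  diag(weights) <- NA_real_
  binary <- !is.na(weights) & weights <= threshold
  binary <- binary & t(binary)
  new("GraphView", nodes = as.character(nodes), binary = binary,
      weights = weights, threshold = threshold)
}

edgeCount <- function(g) sum(g@binary) / 2

asIgraph <- function(g, view = c("binary", "weighted")) {
  view <- match.arg(view)
  if (view == "binary") {
    igraph::graph_from_adjacency_matrix(g@binary * 1, mode = "undirected")
  } else {
    w <- g@weights
    w[is.na(w)] <- 0
    ig <- igraph::graph_from_adjacency_matrix(!is.na(g@weights) * 1,
                                              mode = "undirected")
    idx <- igraph::as_edgelist(ig, names = FALSE)
    igraph::E(ig)$weight <- g@weights[idx]
    ig
  }
}

#' Link density of the binary graph
#'
#' Fraction of realized edges among all node pairs: 2 ne / (nn (nn - 1)).
#'
#' @param g a \linkS4class{GraphView} with at least 2 nodes.
#' @return numeric(1) in [0, 1].
#' @export
linkDensity <- function(g) {
  nn <- length(g@nodes)
  if (nn < 2) stop("contract error: need at least 2 nodes")
  2 * edgeCount(g) / (nn * (nn - 1))
}

#' Average closeness centrality on the weighted graph
#'
#' Per node, the reciprocal of the sum of weighted shortest-path distances
#' (edge length = angle in degrees) to all other nodes; averaged over nodes.
#' A node that cannot reach some other node has an infinite distance sum and
#' hence closeness 0.
#'
#' @param g a \linkS4class{GraphView} with at least 2 nodes.
#' @return numeric(1), nonnegative; halves when all weights double.
#' @export
avgCloseness <- function(g) {
  nn <- length(g@nodes)
  if (nn < 2) stop("contract error: need at least 2 nodes")
  ig <- asIgraph(g, "weighted")
  d <- igraph::distances(ig, algorithm = "dijkstra")
  sums <- rowSums(d)
  mean(ifelse(is.finite(sums), 1 / sums, 0))
}

#' Global clustering coefficient (transitivity) of the binary graph
#'
#' Three times the number of triangles divided by the number of connected
#' node triples; 0 when no connected triple exists.
#'
#' @param g a \linkS4class{GraphView}.
#' @return numeric(1) in [0, 1].
#' @export
clusteringCoeff <- function(g) {
  t <- igraph::transitivity(asIgraph(g, "binary"), type = "global")
  if (is.nan(t)) 0 else t
}

#' Rich-club coefficient of the binary graph
#'
#' With nn_k the nodes of degree strictly greater than k and ne_k the edges
#' among them, returns ne_k / (nn_k (nn_k - 1)); 0 when fewer than two such
#' nodes exist. Note the quotient is used as printed in the feature table,
#' without a factor of 2.
#'
#' @param g a \linkS4class{GraphView}.
#' @param k degree threshold (default: half the node count, rounded down).
#' @return numeric(1), nonnegative.
#' @export
richClub <- function(g, k = floor(length(g@nodes) / 2)) {
  if (k < 0) stop("contract error: k must be >= 0")
  deg <- rowSums(g@binary)
  club <- deg > k
  nnk <- sum(club)
  if (nnk < 2) return(0)
  nek <- sum(g@binary[club, club]) / 2
  nek / (nnk * (nnk - 1))
}

#' S-metric of the binary graph
#'
#' Sum over edges of the product of endpoint degrees.
#'
#' @param g a \linkS4class{GraphView}.
#' @return numeric(1), nonnegative.
#' @export
sMetric <- function(g) {
  deg <- rowSums(g@binary)
  sum((g@binary * outer(deg, deg))[upper.tri(g@binary)])
}

weightedAdjacency <- function(g, transform = c("degrees", "radians", "cosine")) {
  transform <- match.arg(transform)
  present <- !is.na(g@weights)
  w <- g@weights
  w[!present] <- 0
  out <- switch(transform,
                degrees = w,
                radians = w * pi / 180,
                cosine  = cos(w * pi / 180) * present)
  diag(out) <- 0
  out
}

spectralAdjacency <- function(g, mode = c("weighted", "binary"),
                              transform = "degrees") {
  mode <- match.arg(mode)
  if (mode == "binary") g@binary * 1 else weightedAdjacency(g, transform)
}

#' Algebraic connectivity (Fiedler value)
#'
#' Second-smallest eigenvalue of the graph Laplacian L = D - A, where A is
#' the binary or the angle-weighted adjacency. Zero exactly when the graph is
#' disconnected; for the complete binary graph on n nodes it equals n.
#'
#' @param g a \linkS4class{GraphView} with at least 2 nodes.
#' @param mode \code{"weighted"} (default) or \code{"binary"} adjacency.
#' @param transform weight transform for the weighted adjacency:
#'   \code{"degrees"} (default), \code{"radians"}, or \code{"cosine"}.
#' @return numeric(1), nonnegative (tiny negative eigensolver noise is
#'   clamped to 0).
#' @export
algebraicConnectivity <- function(g, mode = c("weighted", "binary"),
                                  transform = "degrees") {
  if (length(g@nodes) < 2) stop("contract error: need at least 2 nodes")
  a <- spectralAdjacency(g, mode, transform)
  l <- diag(rowSums(a)) - a
  ev <- sort(eigen(l, symmetric = TRUE, only.values = TRUE)$values)
  val <- ev[2]
  if (val < 0 && val > -1e-9 * max(1, max(abs(ev)))) val <- 0
  val
}

#' Graph energy
#'
#' Sum of the absolute values of the (real) eigenvalues of the adjacency
#' matrix; the adjacency is symmetric so its spectrum is real.
#'
#' @inheritParams algebraicConnectivity
#' @return numeric(1), nonnegative.
#' @export
graphEnergy <- function(g, mode = c("weighted", "binary"),
                        transform = "degrees") {
  a <- spectralAdjacency(g, mode, transform)
  sum(abs(eigen(a, symmetric = TRUE, only.values = TRUE)$values))
}

#' Feature-extraction configuration
#'
#' @param threshold binarization threshold in degrees (default 45).
#' @param richClubK degree threshold for the rich club; \code{NULL} (default)
#'   means half the node count, rounded down.
#' @param spectralMode adjacency for the spectral features (acg, eng):
#'   \code{"weighted"} (default) or \code{"binary"}.
#' @param weightTransform transform applied to the weighted adjacency for the
#'   spectral features: \code{"degrees"}, \code{"radians"}, \code{"cosine"}.
#' @return list of class \code{"fcnFeatureConfig"}.
#' @export
featureConfig <- function(threshold = 45, richClubK = NULL,
                          spectralMode = c("weighted", "binary"),
                          weightTransform = c("degrees", "radians", "cosine")) {
  structure(list(threshold = threshold,
                 richClubK = richClubK,
                 spectralMode = match.arg(spectralMode),
                 weightTransform = match.arg(weightTransform)),
            class = "fcnFeatureConfig")
}

#' Seven-feature vector of a connectivity network
#'
#' Computes, in this fixed order, link density (ldg), average closeness
#' centrality (acc), global clustering coefficient (gcc), rich-club
#' coefficient (rcc), s-metric (smg), algebraic connectivity (acg) and graph
#' energy (eng) for one connectivity matrix. Count-based features use the
#' binary view; acc uses weighted shortest paths; the spectral features use
#' the view selected in the config.
#'
#' @param m a \linkS4class{ConnectivityMatrix}.
#' @param cfg a \code{\link{featureConfig}}.
#' @return named numeric(7) with the configuration in
#'   \code{attr(, "config")}.
#' @export
featureVector <- function(m, cfg = featureConfig()) {
  g <- toGraph(m, threshold = cfg$threshold)
  k <- if (is.null(cfg$richClubK)) floor(length(g@nodes) / 2) else cfg$richClubK
  out <- c(
    ldg = linkDensity(g),
    acc = avgCloseness(g),
    gcc = clusteringCoeff(g),
    rcc = richClub(g, k = k),
    smg = sMetric(g),
    acg = algebraicConnectivity(g, mode = cfg$spectralMode,
                                transform = cfg$weightTransform),
    eng = graphEnergy(g, mode = cfg$spectralMode,
                      transform = cfg$weightTransform))
  attr(out, "config") <- cfg
  out
}

#' Feature matrix over a set of connectivity networks
#'
#' Stacks the per-segment feature vectors into a features x segments
#' \link[SummarizedExperiment]{SummarizedExperiment} whose colData carries
#' the provenance (subject_id, segment_index) and each segment's mean
#' connectivity angle.
#'
#' @param fcns list of \linkS4class{ConnectivityMatrix}.
#' @param cfg a \code{\link{featureConfig}}.
#' @return SummarizedExperiment with assay \code{"features"} (7 x D).
#' @export
featureMatrix <- function(fcns, cfg = featureConfig()) {
  if (!length(fcns)) stop("contract error: no connectivity matrices supplied")
  vals <- vapply(fcns, featureVector, numeric(7), cfg = cfg)
  if (!all(is.finite(vals))) stop("non-finite feature value encountered")
  cd <- S4Vectors::DataFrame(
    subject_id    = vapply(fcns, function(m) m@subjectID, ""),
    segment_index = vapply(fcns, function(m) m@segmentIndex, 0L),
    mean_angle    = vapply(fcns, meanAngle, 0))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = vals), colData = cd,
    metadata = list(config = cfg))
}

#' Write a feature table as delimited text
#'
#' One row per segment: subject_id, segment_index, then the seven features.
#'
#' @param se SummarizedExperiment from \code{\link{featureMatrix}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFeatureTable <- function(se, path) {
  vals <- t(SummarizedExperiment::assay(se, "features"))
  cd <- SummarizedExperiment::colData(se)
  out <- data.frame(subject_id = cd$subject_id,
                    segment_index = cd$segment_index,
                    vals, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
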