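# Independent brute-force oracles: explicit loops and enumeration only,
# sharing no code path with the package implementations.

oracleAngle <- function(x, y) {
  dot <- 0; nx <- 0; ny <- 0
  for (n in seq_along(x)) {
    dot <- dot + x[n] * y[n]
    nx <- nx + x[n]^2
    ny <- ny + y[n]^2
  }
  acos(max(-1, min(1, dot / (sqrt(nx) * sqrt(ny))))) * 180 / pi
}

# Floyd-Warshall all-pairs shortest paths; w has NA for absent edges.
oracleDistances <- function(w) {
  n <- nrow(w)
  d <- ifelse(is.na(w), Inf, w)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracleCloseness <- function(w) {
  d <- oracleDistances(w)
  vals <- numeric(nrow(w))
  for (i in seq_len(nrow(w))) {
    s <- sum(d[i, -i])
    vals[i] <- if (is.finite(s)) 1 / s else 0
  }
  mean(vals)
}

oracleLinkDensity <- function(bin) {
  nn <- nrow(bin); ne <- 0
  for (i in seq_len(nn - 1)) for (j in (i + 1):nn) if (bin[i, j]) ne <- ne + 1
  2 * ne / (nn * (nn - 1))
}

oracleTransitivity <- function(bin) {
  nn <- nrow(bin)
  triangles <- 0
  if (nn >= 3)
    for (i in 1:(nn - 2)) for (j in (i + 1):(nn - 1)) for (k in (j + 1):nn)
      if (bin[i, j] && bin[j, k] && bin[i, k]) triangles <- triangles + 1
  triples <- 0
  for (v in seq_len(nn)) {
    deg <- sum(bin[v, ])
    triples <- triples + deg * (deg - 1) / 2
  }
  if (triples == 0) 0 else 3 * triangles / triples
}

oracleRichClub <- function(bin, k) {
  deg <- rowSums(bin)
  club <- which(deg > k)
  if (length(club) < 2) return(0)
  ne <- 0
  for (a in seq_along(club)) for (b in seq_along(club))
    if (a < b && bin[club[a], club[b]]) ne <- ne + 1
  ne / (length(club) * (length(club) - 1))
}

oracleSMetric <- function(bin) {
  nn <- nrow(bin)
  deg <- rowSums(bin)
  s <- 0
  for (i in seq_len(nn - 1)) for (j in (i + 1):nn)
    if (bin[i, j]) s <- s + deg[i] * deg[j]
  s
}

oracleAlgebraicConnectivity <- function(adj) {
  n <- nrow(adj)
  l <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    l[i, j] <- if (i == j) sum(adj[i, -i]) else -adj[i, j]
  sort(eigen(l, symmetric = TRUE)$values)[2]
}

oracleEnergy <- function(adj) sum(abs(eigen(adj, symmetric = TRUE)$values))

# Random symmetric angle matrix in (0, 180) with zero diagonal.
randomAngleMatrix <- function(m, seed) {
  set.seed(seed)
  a <- matrix(0, m, m)
  a[upper.tri(a)] <- runif(m * (m - 1) / 2, 1, 179)
  a + t(a)
}

randomConnectivity <- function(m, seed) {
  new("ConnectivityMatrix", channels = paste0("ch", seq_len(m)),
      angles = randomAngleMatrix(m, seed),
      subjectID = "test", segmentIndex = 0L)
}

edgeCountOf <- function(g) sum(g@binary) / 2
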