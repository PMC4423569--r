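test_that("binarization keeps edges at or below the threshold (inclusive)", {
  g <- toyGraph(3, list(list(1, 2, 30), list(1, 3, 45), list(2, 3, 60)))
  expect_equal(edgeCountOf(g), 2)
  all0 <- toGraph(uniformConnectivity(5, 0))
  expect_equal(sum(all0@binary) / 2, 10)
  all90 <- toGraph(uniformConnectivity(5, 90))
  expect_equal(sum(all90@binary) / 2, 0)
})

test_that("linkDensity spans [0, 1] with hand-checkable values", {
  expect_equal(linkDensity(toGraph(uniformConnectivity(5, 10))), 1)
  expect_equal(linkDensity(toGraph(uniformConnectivity(5, 90))), 0)
  path4 <- toyGraph(4, list(list(1, 2, 10), list(2, 3, 10), list(3, 4, 10)))
  expect_equal(linkDensity(path4), 0.5)
})

test_that("avgCloseness matches hand-derived paths and scales inversely", {
  two <- toyGraph(2, list(list(1, 2, 50)))
  expect_equal(avgCloseness(two), 1 / 50)
  tri <- toyGraph(3, list(list(1, 2, 45), list(1, 3, 45), list(2, 3, 45)))
  expect_equal(avgCloseness(tri), 1 / 90)
  triDouble <- toyGraph(3, list(list(1, 2, 90), list(1, 3, 90), list(2, 3, 90)))
  expect_equal(avgCloseness(triDouble), avgCloseness(tri) / 2)
})

test_that("unreachable nodes zero out their closeness", {
  # edge 1-2 plus isolated node 3: nodes cannot all reach each other
  g <- toyGraph(3, list(list(1, 2, 10)))
  expect_equal(avgCloseness(g), 0)
})

test_that("clusteringCoeff reproduces enumerated transitivity", {
  tri <- toyGraph(3, list(list(1, 2, 10), list(2, 3, 10), list(1, 3, 10)))
  expect_equal(clusteringCoeff(tri), 1)
  star <- toyGraph(4, list(list(1, 2, 10), list(1, 3, 10), list(1, 4, 10)))
  expect_equal(clusteringCoeff(star), 0)
  # square plus one diagonal: 2 triangles, 8 connected triples
  sq <- toyGraph(4, list(list(1, 2, 10), list(2, 3, 10), list(3, 4, 10),
                         list(1, 4, 10), list(1, 3, 10)))
  expect_equal(clusteringCoeff(sq), 0.75)
})

test_that("richClub follows the printed quotient without a factor 2", {
  k4 <- toGraph(uniformConnectivity(4, 10))
  expect_equal(richClub(k4, k = 1), 6 / (4 * 3))
  empty <- toGraph(uniformConnectivity(4, 90))
  expect_equal(richClub(empty, k = 0), 0)
  star <- toyGraph(4, list(list(1, 2, 10), list(1, 3, 10), list(1, 4, 10)))
  expect_equal(richClub(star, k = 1), 0)   # only the hub has degree > 1
})

test_that("sMetric sums degree products over edges", {
  path3 <- toyGraph(3, list(list(1, 2, 10), list(2, 3, 10)))
  expect_equal(sMetric(path3), 4)
  expect_equal(sMetric(toGraph(uniformConnectivity(3, 90))), 0)
  tri <- toGraph(uniformConnectivity(3, 10))
  expect_equal(sMetric(tri), 12)
})

test_that("algebraicConnectivity has its known closed forms", {
  for (n in c(3, 5, 7))
    expect_equal(algebraicConnectivity(toGraph(uniformConnectivity(n, 10)),
                                       mode = "binary"), n)
  disconnected <- toyGraph(4, list(list(1, 2, 10), list(3, 4, 10)))
  expect_equal(algebraicConnectivity(disconnected, mode = "binary"), 0)
  path3 <- toyGraph(3, list(list(1, 2, 10), list(2, 3, 10)))
  expect_equal(algebraicConnectivity(path3, mode = "binary"), 1)
})

test_that("graphEnergy matches small closed forms in both modes", {
  single <- toyGraph(2, list(list(1, 2, 37)))
  expect_equal(graphEnergy(single, mode = "weighted"), 74)
  expect_equal(graphEnergy(single, mode = "binary"), 2)
  expect_equal(graphEnergy(toGraph(uniformConnectivity(3, 90)),
                           mode = "binary"), 0)
  k3 <- toGraph(uniformConnectivity(3, 10))
  expect_equal(graphEnergy(k3, mode = "binary"), 4)
})

test_that("every feature matches its brute-force oracle on random graphs", {
  for (seed in 1:60) {
    m <- 3 + seed %% 4   # 3..6 nodes
    cm <- randomConnectivity(m, seed = 1000 + seed)
    g <- toGraph(cm, threshold = 90)  # mixes present/absent binary edges
    bin <- g@binary * 1
    k <- floor(m / 2)
    expect_equal(linkDensity(g), oracleLinkDensity(bin))
    expect_equal(avgCloseness(g), oracleCloseness(g@weights),
                 tolerance = 1e-10)
    expect_equal(clusteringCoeff(g), oracleTransitivity(bin),
                 tolerance = 1e-12)
    expect_equal(richClub(g, k), oracleRichClub(bin, k))
    expect_equal(sMetric(g), oracleSMetric(bin))
    expect_equal(algebraicConnectivity(g, "binary"),
                 max(0, oracleAlgebraicConnectivity(bin)), tolerance = 1e-8)
    w0 <- g@weights; w0[is.na(w0)] <- 0; diag(w0) <- 0
    expect_equal(algebraicConnectivity(g, "weighted"),
                 max(0, oracleAlgebraicConnectivity(w0)), tolerance = 1e-8)
    expect_equal(graphEnergy(g, "binary"), oracleEnergy(bin),
                 tolerance = 1e-8)
    expect_equal(graphEnergy(g, "weighted"), oracleEnergy(w0),
                 tolerance = 1e-8)
  }
})

test_that("adding a binary edge never decreases ldg or smg", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- 6
    cm <- randomConnectivity(m, seed = 300 + seed)
    g <- toGraph(cm, threshold = 60)
    absent <- which(upper.tri(cm@angles) & cm@angles > 60, arr.ind = TRUE)
    if (!nrow(absent)) next
    pick <- absent[sample(nrow(absent), 1), ]
    a2 <- cm@angles
    a2[pick[1], pick[2]] <- a2[pick[2], pick[1]] <- 30
    g2 <- toGraph(new("ConnectivityMatrix", channels = cm@channels,
                      angles = a2, subjectID = "t", segmentIndex = 0L),
                  threshold = 60)
    expect_gte(linkDensity(g2), linkDensity(g))
    expect_gte(sMetric(g2), sMetric(g))
  }
})

test_that("features are invariant under node relabeling", {
  cm <- randomConnectivity(6, seed = 77)
  set.seed(8)
  perm <- sample(6)
  cmp <- new("ConnectivityMatrix", channels = cm@channels,
             angles = cm@angles[perm, perm], subjectID = "t",
             segmentIndex = 0L)
  expect_equal(featureVector(cm), featureVector(cmp), ignore_attr = TRUE)
})

test_that("featureVector composes the seven statistics in order", {
  expect_named(featureVector(randomConnectivity(5, 12)),
               c("ldg", "acc", "gcc", "rcc", "smg", "acg", "eng"))
  all0 <- featureVector(uniformConnectivity(5, 0))
  expect_equal(unname(all0["ldg"]), 1)
  expect_equal(unname(all0["gcc"]), 1)
  all90 <- featureVector(uniformConnectivity(5, 90))
  expect_equal(unname(all90[c("ldg", "smg", "rcc")]), c(0, 0, 0))

  cm <- randomConnectivity(5, seed = 44)
  fv <- featureVector(cm)
  g <- toGraph(cm)
  expect_equal(as.numeric(fv), c(linkDensity(g), avgCloseness(g),
                             clusteringCoeff(g), richClub(g),
                             sMetric(g),
                             algebraicConnectivity(g, "weighted"),
                             graphEnergy(g, "weighted")))
})

test_that("featureMatrix carries provenance and config", {
  fcns <- lapply(1:5, function(i) {
    m <- randomConnectivity(4, seed = i)
    m@subjectID <- paste0("s", (i + 1) %/% 2)
    m@segmentIndex <- as.integer(i)
    m
  })
  se <- featureMatrix(fcns)
  expect_equal(dim(se), c(7L, 5L))
  cd <- SummarizedExperiment::colData(se)
  expect_identical(cd$subject_id, c("s1", "s1", "s2", "s2", "s3"))
  expect_equal(cd$mean_angle, vapply(fcns, meanAngle, 0))
  expect_s3_class(S4Vectors::metadata(se)$config, "fcnFeatureConfig")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(se, path)
  tab <- read.delim(path)
  expect_equal(dim(tab), c(5L, 9L))
})
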