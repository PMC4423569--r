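test_that("firstPC recovers rank-1 structure and duplicates", {
  set.seed(1)
  base <- abs(rnorm(7)) + 0.5
  scale <- runif(12, 0.5, 3)
  u <- outer(base, scale)
  pc <- firstPC(u, standardize = FALSE)
  # rank-1 matrix: scores reproduce the column scale factors up to one factor
  expect_equal(pc$scores / pc$scores[1], scale / scale[1], tolerance = 1e-8)
  u2 <- cbind(u, u[, 3])
  pc2 <- firstPC(u2, standardize = FALSE)
  expect_equal(pc2$scores[3], pc2$scores[13])
})

test_that("firstPC matches a dense SVD oracle on random matrices", {
  for (seed in 1:10) {
    set.seed(seed)
    u <- matrix(rnorm(7 * 50), 7)
    rownames(u) <- c("ldg", "acc", "gcc", "rcc", "smg", "acg", "eng")
    pc <- firstPC(u, standardize = TRUE)
    z <- t(scale(t(u)))
    sv <- svd(z)
    oracle <- as.numeric(crossprod(sv$u[, 1], z))
    if (sv$u[rownames(u) == "ldg", 1] < 0) oracle <- -oracle
    expect_equal(pc$scores, oracle, tolerance = 1e-8)
    expect_gt(pc$loadings["ldg"], 0)
  }
})

test_that("firstPC drops zero-variance features with a warning", {
  set.seed(2)
  u <- rbind(ldg = 0, matrix(rnorm(6 * 20), 6))
  rownames(u)[2:7] <- c("acc", "gcc", "rcc", "smg", "acg", "eng")
  expect_warning(pc <- firstPC(u), "ldg")
  expect_false("ldg" %in% names(pc$loadings))
  expect_error(firstPC(matrix(1, 2, 1)), "at least 2 segments")
})

test_that("fitGMM recovers a well-separated two-Gaussian mixture", {
  set.seed(11)
  x <- c(rnorm(250, -3, 1), rnorm(250, 3, 1))
  fit <- fitGMM(x, seed = 11L)
  mu <- sort(fit@means)
  expect_lt(abs(mu[1] - (-3)), 0.3)
  expect_lt(abs(mu[2] - 3), 0.3)
  expect_equal(sum(fit@weights), 1)
  expect_true(all(diff(fit@logLikTrace) > -1e-8 * abs(fit@logLik)))
  expect_true(fit@converged)
})

test_that("fitGMM agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  set.seed(12)
  x <- c(rnorm(200, 0, 1), rnorm(200, 5, 1.5))
  fit <- fitGMM(x)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller frame
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit@means), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit@logLik, mc$loglik, tolerance = 1e-3)
})

test_that("fitGMM rejects degenerate inputs", {
  expect_error(fitGMM(rep(1, 50)), "distinct")
  expect_error(fitGMM(c(1, 2, 3)), "distinct")
})

test_that("labelSegments is nearest-mean with ties to component 1", {
  fit <- new("GaussianMixture2", weights = c(0.5, 0.5), means = c(-2, 4),
             variances = c(1, 1), logLik = 0, logLikTrace = 0,
             iterations = 1L, converged = TRUE, seed = 1L)
  expect_equal(labelSegments(fit, c(-2, 4)), c(1L, 2L))
  expect_equal(labelSegments(fit, 1), 1L)      # exact midpoint -> component 1
  x <- seq(-5, 7, by = 0.3)
  oracle <- ifelse(abs(x - 4) < abs(x + 2), 2L, 1L)
  expect_equal(labelSegments(fit, x), oracle)
})

test_that("posterior labelling weighs mixture weights and variances", {
  fit <- new("GaussianMixture2", weights = c(0.9, 0.1), means = c(0, 2),
             variances = c(1, 1), logLik = 0, logLikTrace = 0,
             iterations = 1L, converged = TRUE, seed = 1L)
  # at the midpoint the heavier component wins under posterior assignment
  expect_equal(labelSegments(fit, 1, method = "posterior"), 1L)
})

test_that("components acquire clinical identity via mean connectivity angle", {
  labels <- c(1L, 1L, 2L, 2L)
  out <- mapComponentsToClasses(labels, c(44, 45, 58, 57))
  expect_equal(out, c("control", "control", "epileptic", "epileptic"),
               ignore_attr = TRUE)
  # invariant to swapping component indices
  out2 <- mapComponentsToClasses(3L - labels, c(44, 45, 58, 57))
  expect_equal(unclass(out2), unclass(out), ignore_attr = TRUE)
  expect_error(mapComponentsToClasses(c(1L, 1L), c(40, 50)), "inconclusive")
  expect_error(mapComponentsToClasses(c(1L, 2L), c(50, 50)), "inconclusive")
})

test_that("subjectProbability reproduces worked percentage examples", {
  ids <- c(rep("PE01", 14), rep("PC01", 11), rep("PE09", 25))
  labs <- c(rep("epileptic", 12), rep("control", 2),
            rep("control", 11),
            rep("epileptic", 25))
  rep <- subjectProbability(ids, labs)
  expect_equal(rep$probability_pct[rep$subject_id == "PE01"], 86L)
  expect_equal(rep$probability_pct[rep$subject_id == "PC01"], 0L)
  expect_equal(rep$probability_pct[rep$subject_id == "PE09"], 100L)
  expect_true(all(rep$e_s <= rep$d_s))
})

test_that("subjectProbability is invariant to segment order", {
  set.seed(5)
  ids <- sample(rep(c("a", "b"), c(10, 6)))
  labs <- sample(c("epileptic", "control"), 16, replace = TRUE)
  perm <- sample(16)
  r1 <- subjectProbability(ids, labs)
  r2 <- subjectProbability(ids[perm], labs[perm])
  r2 <- r2[match(r1$subject_id, r2$subject_id), ]
  expect_equal(r1$probability, r2$probability)
})

test_that("classifySubject thresholds the probability inclusively", {
  rep <- S4Vectors::DataFrame(subject_id = c("a", "b", "c", "d"),
                              probability = c(0.86, 0.25, 0.11, 0.5))
  out <- classifySubject(rep, threshold = 0.5)
  expect_equal(out$call, c("epileptic", "control", "control", "epileptic"))
  expect_error(classifySubject(rep, threshold = 0), "configuration")
  expect_error(classifySubject(rep, threshold = 1), "configuration")
})

test_that("confusionMetrics computes the standard 2x2 panel", {
  calls <- c(rep("epileptic", 9), rep("control", 2), rep("control", 7))
  truth <- c(rep("epilepsy", 11), rep("control", 7))
  m <- confusionMetrics(calls, truth)
  expect_equal(unname(m[c("sensitivity", "specificity", "accuracy",
                          "ppv", "npv")]),
               c(81.8, 100, 88.9, 100, 77.8))
  perfect <- confusionMetrics(truth, truth)
  expect_equal(unname(perfect[c("sensitivity", "specificity", "accuracy")]),
               c(100, 100, 100))
  allPos <- confusionMetrics(rep("epileptic", 18), truth)
  expect_equal(unname(allPos["specificity"]), 0)
  expect_error(confusionMetrics(calls, rep("epilepsy", 18)), "truth class")
})

test_that("linear SVM separates separable clusters and rejects one class", {
  set.seed(9)
  train <- cbind(matrix(rnorm(7 * 30, 0), 7), matrix(rnorm(7 * 30, 6), 7))
  labels <- rep(c("control", "epileptic"), each = 30)
  test <- cbind(matrix(rnorm(7 * 10, 0), 7), matrix(rnorm(7 * 10, 6), 7))
  pred <- svmSupervised(train, labels, test)
  expect_equal(pred, rep(c("control", "epileptic"), each = 10))
  expect_equal(svmSupervised(train, labels, train), labels)
  expect_error(svmSupervised(train, rep("control", 60), test), "both classes")
})

test_that("model dump serializes every fitted parameter", {
  set.seed(3)
  fit <- fitGMM(c(rnorm(50, -2), rnorm(50, 2)), seed = 3L)
  path <- withr::local_tempfile(fileext = ".txt")
  writeModelDump(fit, path)
  kv <- readLines(path)
  expect_true(any(grepl("^mean1=", kv)))
  expect_true(any(grepl("^seed=3$", kv)))
  expect_length(kv, 10)
})
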