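test_that("groupMeanTest reports pooled degrees of freedom n1 + n2 - 2", {
  set.seed(1)
  a <- runif(171, 30, 60); b <- runif(171, 45, 75)
  out <- groupMeanTest(a, b)
  expect_equal(out$df, 340)
  expect_lt(out$p, 1)
})

test_that("groupMeanTest matches the closed-form pooled t on hand vectors", {
  out <- groupMeanTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(out$t, 3), -3.674)
  expect_equal(out$df, 4)
  # textbook closed form
  sp <- sqrt(((3 - 1) * 1 + (3 - 1) * 1) / 4)
  expect_equal(out$t, (2 - 5) / (sp * sqrt(1 / 3 + 1 / 3)))
  same <- groupMeanTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(groupMeanTest(1, c(1, 2)), "at least 2")
})

test_that("edgewiseTests flags a strongly shifted pair and keeps bookkeeping", {
  set.seed(42)
  nseg <- 30; np <- 12
  a <- matrix(rnorm(nseg * np, 50, 2), nseg)
  b <- matrix(rnorm(nseg * np, 50, 2), nseg)
  b[, 5] <- b[, 5] + 20   # 10 sd shift
  colnames(a) <- colnames(b) <- paste0("p", 1:np)
  res <- edgewiseTests(a, b)
  expect_equal(nrow(res), np)
  expect_true(res$significant[5])
  expect_equal(sum(res$significant), 1)
  expect_identical(res$pair, paste0("p", 1:np))
})

test_that("zero-variance pairs are reported untestable and excluded", {
  set.seed(7)
  a <- matrix(rnorm(20), 10, 2); b <- matrix(rnorm(20), 10, 2)
  a[, 2] <- 45; b[, 2] <- 45
  expect_warning(res <- edgewiseTests(a, b), "untestable")
  expect_false(res$testable[2])
  expect_false(res$significant[2])
  expect_true(is.na(res$t[2]))
  expect_equal(sum(res$testable), 1)
})

test_that("classical Bonferroni option divides alpha by testable pairs", {
  set.seed(13)
  a <- matrix(rnorm(200, 50, 2), 20)
  b <- matrix(rnorm(200, 50, 2), 20)
  b[, 1] <- b[, 1] + 20
  raw <- edgewiseTests(a, b, alphaAdj = 0.05, bonferroni = FALSE)
  bon <- edgewiseTests(a, b, alphaAdj = 0.05, bonferroni = TRUE)
  expect_true(bon$significant[1])
  expect_lte(sum(bon$significant), sum(raw$significant))
})

test_that("significance mask is the symmetric Fig-3e style 0/1 matrix", {
  ch <- paste0("e", 1:4)
  tests <- data.frame(pair = pairLabels(ch), t = 0, p = 1,
                      significant = c(TRUE, rep(FALSE, 4), TRUE),
                      testable = TRUE)
  mask <- significanceMask(tests, ch)
  expect_identical(mask, t(mask))
  expect_equal(mask["e1", "e2"], 1L)
  expect_equal(mask["e3", "e4"], 1L)
  expect_equal(sum(mask), 4L)
})

test_that("hemisphereDensity partitions strong edges as counted by hand", {
  m <- uniformConnectivity(19, 0, channels = defaultMontage()@requiredChannels)
  expect_equal(hemisphereDensity(m),
               c(right = 28, left = 28, inter = 64))
  m90 <- uniformConnectivity(19, 90,
                             channels = defaultMontage()@requiredChannels)
  expect_equal(hemisphereDensity(m90), c(right = 0, left = 0, inter = 0))

  ch <- defaultMontage()@requiredChannels
  a <- matrix(90, 19, 19); diag(a) <- 0
  i <- which(ch == "c3"); j <- which(ch == "c4")
  a[i, j] <- a[j, i] <- 30
  single <- new("ConnectivityMatrix", channels = ch, angles = a,
                subjectID = "t", segmentIndex = 0L)
  expect_equal(hemisphereDensity(single), c(right = 0, left = 0, inter = 1))
})

test_that("midline handling and partition coverage behave as documented", {
  ch <- defaultMontage()@requiredChannels
  a <- matrix(90, 19, 19); diag(a) <- 0
  i <- which(ch == "cz"); j <- which(ch == "c3")
  a[i, j] <- a[j, i] <- 30
  m <- new("ConnectivityMatrix", channels = ch, angles = a,
           subjectID = "t", segmentIndex = 0L)
  expect_equal(sum(hemisphereDensity(m)), 0)            # excluded by default
  expect_equal(hemisphereDensity(m, midline = "inter")[["inter"]], 1)
  bad <- uniformConnectivity(3, 10, channels = c("zz1", "zz2", "zz3"))
  expect_error(hemisphereDensity(bad), "absent from montage")
})

test_that("hemisphere counts are invariant to within-hemisphere relabeling", {
  spec <- defaultMontage()
  m <- randomConnectivity(19, seed = 31)
  m@channels <- spec@requiredChannels
  base <- hemisphereDensity(m)
  # swap two left-hemisphere electrodes (rows/cols move with their labels)
  ch <- m@channels
  i <- which(ch == "f3"); j <- which(ch == "p3")
  perm <- seq_len(19); perm[c(i, j)] <- c(j, i)
  m2 <- new("ConnectivityMatrix", channels = ch[perm],
            angles = m@angles[perm, perm], subjectID = "t",
            segmentIndex = 0L)
  expect_equal(hemisphereDensity(m2), base)
})

test_that("per-subject density summary averages across segments", {
  spec <- defaultMontage()
  fcns <- lapply(1:4, function(i) {
    m <- randomConnectivity(19, seed = 400 + i)
    m@channels <- spec@requiredChannels
    m
  })
  s <- hemisphereDensitySummary(fcns)
  expect_identical(s$category, c("right", "left", "inter"))
  counts <- t(vapply(fcns, hemisphereDensity, numeric(3)))
  expect_equal(s$mean, unname(colMeans(counts)))
})
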