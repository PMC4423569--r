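#' First principal component of a feature matrix
#'
#' Projects the segments onto the leading principal axis of the (optionally
#' z-scored) features x segments matrix, computed by singular value
#' decomposition. The seven features span several orders of magnitude, so
#' standardization is on by default; zero-variance features are dropped with
#' a warning before scaling. The sign is fixed so that the loading on
#' \code{ldg} is positive (falling back to the first retained feature with a
#' nonzero loading), giving "larger score" a stable meaning across runs.
#'
#' @param u features x segments numeric matrix, or the SummarizedExperiment
#'   from \code{\link{featureMatrix}}; needs at least 2 columns.
#' @param standardize z-score each feature across segments first (default
#'   TRUE).
#' @return list with \code{scores} (length D), \code{loadings} (named, on the
#'   retained features), \code{dropped} (names of zero-variance features) and
#'   \code{varianceExplained}.
#' @export
firstPC <- function(u, standardize = TRUE) {
  if (is(u, "SummarizedExperiment"))
    u <- SummarizedExperiment::assay(u, "features")
  u <- as.matrix(u)
  if (ncol(u) < 2) stop("contract error: need at least 2 segments")
  if (is.null(rownames(u))) rownames(u) <- paste0("f", seq_len(nrow(u)))
  dropped <- character()
  if (standardize) {
    sds <- apply(u, 1L, stats::sd)
    zero <- sds == 0
    if (any(zero)) {
      dropped <- rownames(u)[zero]
      warning("dropping zero-variance feature(s) before standardization: ",
              paste(dropped, collapse = ", "))
      u <- u[!zero, , drop = FALSE]
      sds <- sds[!zero]
      if (!nrow(u)) stop("all features have zero variance")
    }
    u <- (u - rowMeans(u)) / sds
  }
  sv <- svd(u, nu = 1, nv = 1)
  loadings <- sv$u[, 1]
  names(loadings) <- rownames(u)
  scores <- as.numeric(crossprod(loadings, u))
  anchor <- if ("ldg" %in% names(loadings) && loadings["ldg"] != 0)
    loadings["ldg"] else loadings[which(loadings != 0)[1]]
  if (length(anchor) && isTRUE(anchor < 0)) {
    loadings <- -loadings
    scores <- -scores
  }
  list(scores = scores, loadings = loadings, dropped = dropped,
       varianceExplained = sv$d[1]^2 / sum(svd(u, nu = 0, nv = 0)$d^2))
}

gmmLogLik <- function(x, w, mu, s2) {
  comp <- vapply(1:2, function(i)
    log(w[i]) + stats::dnorm(x, mu[i], sqrt(s2[i]), log = TRUE),
    numeric(length(x)))
  mx <- pmax(comp[, 1], comp[, 2])
  sum(mx + log(exp(comp[, 1] - mx) + exp(comp[, 2] - mx)))
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Maximum-likelihood fit of \eqn{p(x) = \omega_1 N(\mu_1, \sigma_1^2) +
#' \omega_2 N(\mu_2, \sigma_2^2)} by expectation-maximization.
#' Initialization is deterministic: component means start at the means of the
#' lowest and highest quartiles of the data, both variances at the overall
#' variance, weights at 1/2. Variances are floored at
#' \code{varFloor * var(x)} to prevent collapse. The log-likelihood is
#' tracked per iteration and is non-decreasing.
#'
#' @param x numeric scores with at least 4 distinct values.
#' @param seed integer recorded in the fit metadata (the fit itself is
#'   deterministic given the data).
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param maxIter maximum EM iterations (default 500).
#' @param varFloor variance floor as a fraction of \code{var(x)}
#'   (default 1e-6).
#' @return A \linkS4class{GaussianMixture2}.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(100, -3), rnorm(100, 3))
#' fitGMM(x)
#' @export
fitGMM <- function(x, seed = 1L, tol = 1e-8, maxIter = 500L, varFloor = 1e-6) {
  x <- as.numeric(x)
  if (length(unique(x)) < 4)
    stop("fit error: need at least 4 distinct score values")
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  mu <- c(mean(x[x <= q[1]]), mean(x[x >= q[2]]))
  v0 <- stats::var(x)
  if (v0 == 0) stop("fit error: degenerate (constant) scores")
  s2 <- c(v0, v0)
  w <- c(0.5, 0.5)
  floorVal <- varFloor * v0
  ll <- gmmLogLik(x, w, mu, s2)
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    # E-step: responsibilities via log-sum-exp
    lc <- vapply(1:2, function(i)
      log(w[i]) + stats::dnorm(x, mu[i], sqrt(s2[i]), log = TRUE),
      numeric(length(x)))
    mx <- pmax(lc[, 1], lc[, 2])
    den <- mx + log(exp(lc[, 1] - mx) + exp(lc[, 2] - mx))
    r1 <- exp(lc[, 1] - den)
    # M-step
    n1 <- sum(r1); n2 <- length(x) - n1
    if (min(n1, n2) < 1e-12)
      stop("fit error: a mixture component collapsed to zero weight")
    w <- c(n1, n2) / length(x)
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    s2 <- c(sum(r1 * (x - mu[1])^2) / n1,
            sum((1 - r1) * (x - mu[2])^2) / n2)
    s2 <- pmax(s2, floorVal)
    llNew <- gmmLogLik(x, w, mu, s2)
    trace <- c(trace, llNew)
    if (llNew - ll < tol * abs(ll) && llNew - ll >= -1e-10 * abs(ll)) {
      ll <- llNew
      converged <- TRUE
      break
    }
    ll <- llNew
  }
  new("GaussianMixture2", weights = w, means = mu, variances = s2,
      logLik = ll, logLikTrace = trace, iterations = iter,
      converged = converged, seed = as.integer(seed))
}

#' Assign segments to mixture components
#'
#' Hard assignment of each score to the component with the nearer mean
#' (absolute distance on the score axis; ties go to component 1), or to the
#' component with the larger posterior responsibility.
#'
#' @param model a \linkS4class{GaussianMixture2}.
#' @param x numeric scores.
#' @param method \code{"nearest"} (default) or \code{"posterior"}.
#' @return integer vector of component indices (1 or 2).
#' @export
labelSegments <- function(model, x, method = c("nearest", "posterior")) {
  method <- match.arg(method)
  if (method == "nearest") {
    d1 <- abs(x - model@means[1])
    d2 <- abs(x - model@means[2])
    ifelse(d2 < d1, 2L, 1L)
  } else {
    l1 <- log(model@weights[1]) +
      stats::dnorm(x, model@means[1], sqrt(model@variances[1]), log = TRUE)
    l2 <- log(model@weights[2]) +
      stats::dnorm(x, model@means[2], sqrt(model@variances[2]), log = TRUE)
    ifelse(l2 > l1, 2L, 1L)
  }
}

#' Give mixture components a clinical identity
#'
#' The unsupervised clustering yields anonymous components; the component
#' whose member segments show the larger mean connectivity angle (weaker
#' overall coupling) is labelled "epileptic", matching the direction of the
#' group difference the method is built on (the epilepsy group exhibits
#' larger mean angles than controls).
#'
#' @param componentLabels integer component index (1/2) per segment.
#' @param segmentMeanAngles mean connectivity angle (degrees) per segment,
#'   e.g. \code{colData(se)$mean_angle} or \code{\link{meanAngle}} applied to
#'   each matrix.
#' @return character vector per segment, \code{"epileptic"} or
#'   \code{"control"}, with the component-to-class map in
#'   \code{attr(, "mapping")}.
#' @export
mapComponentsToClasses <- function(componentLabels, segmentMeanAngles) {
  if (length(componentLabels) != length(segmentMeanAngles))
    stop("contract error: labels and mean angles must align")
  if (!all(1:2 %in% componentLabels))
    stop("mapping error: inconclusive clustering (a component is empty)")
  m1 <- mean(segmentMeanAngles[componentLabels == 1L])
  m2 <- mean(segmentMeanAngles[componentLabels == 2L])
  if (m1 == m2)
    stop("mapping error: inconclusive clustering (equal component mean angles)")
  epiComp <- if (m1 > m2) 1L else 2L
  mapping <- c("control", "control")
  mapping[epiComp] <- "epileptic"
  out <- mapping[componentLabels]
  attr(out, "mapping") <- stats::setNames(mapping, c("component1", "component2"))
  out
}

#' Per-subject epilepsy probability
#'
#' For each subject, the probability of being epileptic is the fraction of
#' that subject's segments labelled epileptic: E_s / D_s. The percentage
#' column rounds to the nearest integer for display.
#'
#' @param subjectIDs character subject id per segment.
#' @param classLabels \code{"epileptic"}/\code{"control"} per segment.
#' @return \link[S4Vectors]{DataFrame} with one row per subject: subject_id,
#'   e_s, d_s, probability, probability_pct.
#' @export
subjectProbability <- function(subjectIDs, classLabels) {
  if (length(subjectIDs) != length(classLabels) || !length(subjectIDs))
    stop("contract error: need aligned, nonempty subject ids and labels")
  ids <- unique(subjectIDs)
  es <- vapply(ids, function(s)
    sum(classLabels[subjectIDs == s] == "epileptic"), 0L)
  ds <- vapply(ids, function(s) sum(subjectIDs == s), 0L)
  S4Vectors::DataFrame(
    subject_id = ids,
    e_s = es,
    d_s = ds,
    probability = es / ds,
    probability_pct = as.integer(round(100 * es / ds)))
}

#' Binary subject call from the epilepsy probability
#'
#' @param report DataFrame from \code{\link{subjectProbability}} (or any with
#'   a \code{probability} column).
#' @param threshold decision threshold in (0, 1); a subject is called
#'   epileptic when its probability is at or above it. Default 0.5.
#' @return the report with an added \code{call} column
#'   ("epileptic"/"control").
#' @export
classifySubject <- function(report, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("configuration error: threshold must lie in (0, 1)")
  report$call <- ifelse(report$probability >= threshold,
                        "epileptic", "control")
  report
}

#' Diagnostic confusion metrics
#'
#' Standard 2x2 screening metrics, in percent rounded to one decimal:
#' sensitivity, specificity, accuracy, positive and negative predictive
#' value. "Epileptic" is the positive class.
#'
#' @param calls predicted labels ("epileptic"/"control").
#' @param truth ground-truth labels ("epilepsy"/"control"; "epileptic" is
#'   accepted too).
#' @return named numeric with sensitivity, specificity, accuracy, ppv, npv
#'   (percent) and the raw counts tp, fn, tn, fp.
#' @export
confusionMetrics <- function(calls, truth) {
  if (length(calls) != length(truth))
    stop("contract error: calls and truth must align")
  pos <- startsWith(as.character(truth), "epi")
  hat <- startsWith(as.character(calls), "epi")
  if (!any(pos) || all(pos))
    stop("contract error: need at least one subject per truth class")
  tp <- sum(hat & pos); fn <- sum(!hat & pos)
  tn <- sum(!hat & !pos); fp <- sum(hat & !pos)
  pct <- function(a, b) round(100 * a / b, 1)
  c(sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    accuracy    = pct(tp + tn, tp + fn + tn + fp),
    ppv         = if (tp + fp > 0) pct(tp, tp + fp) else NA_real_,
    npv         = if (tn + fn > 0) pct(tn, tn + fn) else NA_real_,
    tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Supervised linear-SVM segment classifier (comparator)
#'
#' Optional supervised baseline: a linear-kernel support vector machine
#' trained on labelled feature vectors, predicting segment labels for a test
#' matrix. Complements the unsupervised mixture pipeline when a small
#' annotated training set is available.
#'
#' @param trainU features x segments training matrix.
#' @param trainLabels factor or character label per training segment; both
#'   classes must be present.
#' @param testU features x segments test matrix.
#' @return character vector of predicted labels for the test columns.
#' @export
svmSupervised <- function(trainU, trainLabels, testU) {
  trainLabels <- factor(trainLabels)
  if (nlevels(trainLabels) < 2)
    stop("fit error: training set must contain both classes")
  fit <- e1071::svm(x = t(as.matrix(trainU)), y = trainLabels,
                    kernel = "linear", scale = TRUE)
  as.character(stats::predict(fit, t(as.matrix(testU))))
}

#' Write subject reports as delimited text
#'
#' @param report DataFrame from \code{\link{classifySubject}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSubjectReports <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dump mixture-model parameters as structured text
#'
#' @param model a \linkS4class{GaussianMixture2}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeModelDump <- function(model, path) {
  lines <- c(
    sprintf("weight1=%.10g", model@weights[1]),
    sprintf("weight2=%.10g", model@weights[2]),
    sprintf("mean1=%.10g", model@means[1]),
    sprintf("mean2=%.10g", model@means[2]),
    sprintf("variance1=%.10g", model@variances[1]),
    sprintf("variance2=%.10g", model@variances[2]),
    sprintf("logLik=%.10g", model@logLik),
    sprintf("iterations=%d", model@iterations),
    sprintf("converged=%s", model@converged),
    sprintf("seed=%d", model@seed))
  writeLines(lines, path)
  invisible(path)
}
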