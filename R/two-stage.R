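# Two-stage extreme vs non-extreme classification.  Stage one is any fitted
# extreme-class model; stage two regresses the binary extreme indicator on
# the per-sample maximum class-membership probability with a scalar logistic
# model.  Extreme samples concentrate probability on one class (maxima near
# 1); feature-wise mixtures spread it across their two parents (maxima near
# 1/2), which is what the logistic threshold exploits.

#' Maxima of class-membership probabilities
#'
#' @param model a fitted extreme-class classifier.
#' @param pset a [PhenotypeSet-class] of extreme and/or non-extreme samples.
#'   When labels are present, a label equal to one of the model's classes
#'   marks the sample as extreme; any other label as non-extreme.
#' @return a [MaximaScores-class].
#' @export
probabilityMaxima <- function(model, pset) {
  proba <- predictProba(model, pset)
  score <- apply(proba, 1, max)
  labels <- phenoLabels(pset)
  isExtreme <- if (is.null(labels)) rep(NA, length(score))
               else labels %in% model@classLevels
  method <- if (is(model, "ForestModel")) "rf" else model@method
  new("MaximaScores", sampleIds = rownames(proba), score = unname(score),
      sourceMethod = method, isExtreme = isExtreme)
}

# scalar logistic regression by Newton-Raphson; ridge > 0 adds an L2 penalty
# on (intercept, slope), which keeps the Hessian invertible under perfect
# separation
.logisticNewton <- function(x, y, ridge = 0, tol = 1e-8, maxIter = 100L) {
  X <- cbind(1, x)
  beta <- c(0, 0)
  for (it in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- p * (1 - p)
    grad <- drop(crossprod(X, y - p)) - ridge * beta
    H <- crossprod(X * w, X) + diag(ridge, 2)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) return(list(beta = beta, converged = FALSE))
    beta <- beta + step
    if (max(abs(grad)) < tol)
      return(list(beta = beta, converged = TRUE))
    if (any(!is.finite(beta)) || max(abs(beta)) > 1e6)
      return(list(beta = beta, converged = FALSE))
  }
  list(beta = beta, converged = FALSE)
}

.fitScalarLogistic <- function(x, y) {
  fit <- .logisticNewton(x, y)
  separated <- !fit$converged || max(abs(fit$beta)) > 30
  if (separated) fit <- .logisticNewton(x, y, ridge = 1e-6)
  list(beta = fit$beta, separated = separated)
}

#' Logistic extreme-vs-non-extreme model on maxima scores
#'
#' Maximum-likelihood scalar logistic regression of the extreme indicator on
#' the probability-maxima score (Newton iterations, tolerance 1e-8).  Perfect
#' separation, where the MLE diverges, falls back to a tiny L2 ridge (1e-6)
#' and is flagged.  Stratified 10-fold cross-validation records fold
#' accuracies and out-of-fold posteriors at the classification threshold.
#'
#' @param scores a [MaximaScores-class] with known truth (`isExtreme`).
#' @param nFolds cross-validation folds (default 10).
#' @param seed fold-assignment seed.
#' @param threshold posterior classification threshold (default 0.5).
#' @return a [BinaryModel-class].
#' @export
fitBinary <- function(scores, nFolds = 10L, seed = 1L, threshold = 0.5) {
  y <- as.numeric(scores@isExtreme)
  if (anyNA(y)) stop("truth (isExtreme) required for every sample")
  if (length(unique(y)) < 2) stop("both classes must be present")
  x <- scores@score
  full <- .fitScalarLogistic(x, y)
  fold <- .stratifiedFolds(ifelse(y == 1, "e", "n"), nFolds, seed)
  acc <- numeric(nFolds)
  oof <- setNames(rep(NA_real_, length(x)), scores@sampleIds)
  for (f in seq_len(nFolds)) {
    tr <- fold != f
    cv <- .fitScalarLogistic(x[tr], y[tr])
    p <- plogis(cv$beta[1] + cv$beta[2] * x[!tr])
    oof[!tr] <- p
    acc[f] <- mean((p >= threshold) == (y[!tr] == 1))
  }
  new("BinaryModel", intercept = unname(full$beta[1]),
      slope = unname(full$beta[2]),
      threshold = threshold, cvAccuracies = acc, cvPredictions = oof,
      auc = rocAuc(x, y == 1), separated = full$separated,
      sourceMethod = scores@sourceMethod)
}

#' Mann-Whitney ROC AUC
#'
#' The probability that a random extreme sample scores above a random
#' non-extreme sample, counting ties as one half — the exact U-statistic
#' over all cross-pairs, computed from midranks.
#'
#' @param score numeric scores.
#' @param truth logical (TRUE = positive class); both classes present.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(score)  # midranks implement the half-credit tie convention
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit and select the best two-stage model per base method
#'
#' For each supplied extreme-class model, scores all samples with
#' [probabilityMaxima()], fits `nCandidates` logistic models differing in
#' their cross-validation fold seed, and keeps the candidate with the highest
#' mean CV accuracy (ties go to the higher AUC).  Sensitivity and specificity
#' are reported from the winning candidate's out-of-fold posteriors at the
#' threshold.
#'
#' @param models named list of fitted extreme-class classifiers (e.g.
#'   `list(lasso = ..., enet = ..., rf = ...)`).
#' @param extreme,nonextreme labeled [PhenotypeSet-class] cohorts; both must
#'   share the models' features.
#' @param nCandidates candidate models per method (default 10).
#' @param seed base seed; candidate i uses fold seed `seed + i`.
#' @param threshold posterior threshold (default 0.5).
#' @return named list per method:
#'   `list(model, scores, sensitivity, specificity, auc)`.
#' @export
twoStageClassifier <- function(models, extreme, nonextreme,
                               nCandidates = 10L, seed = 1L,
                               threshold = 0.5) {
  stopifnot(length(models) >= 1)
  m <- rbind(traitMatrix(extreme), traitMatrix(nonextreme))
  combined <- PhenotypeSet(m, labels = c(phenoLabels(extreme),
                                         phenoLabels(nonextreme)))
  out <- list()
  for (nm in names(models)) {
    scores <- probabilityMaxima(models[[nm]], combined)
    cands <- lapply(seq_len(nCandidates), function(i)
      fitBinary(scores, seed = seed + i, threshold = threshold))
    best <- selectBestTwoStage(cands)
    y <- scores@isExtreme
    pred <- best@cvPredictions >= threshold
    out[[nm]] <- list(model = best, scores = scores,
                      sensitivity = mean(pred[y]),
                      specificity = mean(!pred[!y]),
                      auc = best@auc)
  }
  out
}

#' Pick the best two-stage candidate
#'
#' @param candidates list of [BinaryModel-class] candidates (>= 1).
#' @return the candidate with the highest mean CV accuracy; ties go to the
#'   higher AUC, then the earlier candidate.
#' @export
selectBestTwoStage <- function(candidates) {
  stopifnot(length(candidates) >= 1)
  means <- vapply(candidates, function(m) mean(m@cvAccuracies), numeric(1))
  aucs <- vapply(candidates, function(m) m@auc, numeric(1))
  candidates[[order(-means, -aucs)[1]]]
}
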