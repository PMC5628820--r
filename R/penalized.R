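# Penalized multinomial classifiers.  Both models minimize the multinomial
# deviance plus lambda * [ (1 - alpha) ||beta||^2 / 2 + alpha ||beta||_1 ]
# (glmnet's elastic-net penalty); alpha = 1 is the LASSO.  lambda is tuned by
# stratified 10-fold cross-validated misclassification error along a 100-step
# descending log path from lambda_max down to lambda_max * 1e-4, with ties
# resolved toward stronger regularization (larger lambda, then larger alpha).

.checkTrainable <- function(labels, nFolds) {
  if (is.null(labels)) stop("labels required")
  counts <- table(labels)
  if (length(counts) < 2) stop("degenerate training data: a single class")
  if (any(counts < nFolds))
    stop("every class needs at least 'nFolds' samples")
}

.cvGlmnetAt <- function(X, y, alpha, foldid) {
  glmnet::cv.glmnet(X, y, family = "multinomial", alpha = alpha,
                    type.measure = "class", foldid = foldid,
                    nlambda = 100, lambda.min.ratio = 1e-4)
}

.penalizedFromCv <- function(cvfit, alpha, method, enc, classLevels, cvPath) {
  lambda <- cvfit$lambda.min  # largest lambda among error ties
  cf <- coef(cvfit$glmnet.fit, s = lambda)
  nz <- unique(unlist(lapply(cf, function(b) {
    rn <- rownames(b)[which(b[, 1] != 0)]
    setdiff(rn, "(Intercept)")
  })))
  selected <- unique(unname(enc@parent[nz]))
  new("PenalizedModel", method = method, alpha = alpha, lambda = lambda,
      fit = cvfit$glmnet.fit, encoding = enc@encoding,
      classLevels = classLevels,
      selectedFeatures = selected[order(match(selected, names(enc@encoding)))],
      cvPath = cvPath)
}

#' Fit a multinomial LASSO classifier
#'
#' L1-penalized multinomial regression on the dummy-coded traits.  `lambda`
#' is chosen as the value minimizing the mean stratified `nFolds`-fold
#' cross-validated misclassification error (ties go to the largest lambda);
#' the model is then refit on all training data at that lambda.
#'
#' @param pset a labeled, preprocessed [PhenotypeSet-class] with at least
#'   `nFolds` samples per class.
#' @param nFolds cross-validation folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @return a [PenalizedModel-class] with `method = "lasso"`.
#' @export
fitLasso <- function(pset, nFolds = 10L, seed = 1L) {
  labels <- phenoLabels(pset)
  .checkTrainable(labels, nFolds)
  enc <- encodeDesign(pset)
  classLevels <- sort(unique(labels))
  y <- factor(labels, levels = classLevels)
  foldid <- .stratifiedFolds(labels, nFolds, seed)
  cvfit <- .cvGlmnetAt(enc@X, y, alpha = 1, foldid = foldid)
  cvPath <- data.frame(alpha = 1, lambda = cvfit$lambda, error = cvfit$cvm)
  .penalizedFromCv(cvfit, 1, "lasso", enc, classLevels, cvPath)
}

#' Fit a multinomial elastic-net classifier
#'
#' Two-dimensional tuning: for each alpha on the canonical 11-point grid
#' 0, 0.1, ..., 1 (with 0 floored to 0.01 so the penalty stays selective;
#' pure ridge never zeroes a coefficient), the lambda cross-validation of
#' [fitLasso()] is run with the same folds; the (alpha, lambda) pair with
#' minimum cross-validated misclassification error wins, ties resolved to
#' the larger alpha and then the larger lambda.
#'
#' @inheritParams fitLasso
#' @return a [PenalizedModel-class] with `method = "enet"`.
#' @export
fitEnet <- function(pset, nFolds = 10L, seed = 1L) {
  labels <- phenoLabels(pset)
  .checkTrainable(labels, nFolds)
  enc <- encodeDesign(pset)
  classLevels <- sort(unique(labels))
  y <- factor(labels, levels = classLevels)
  foldid <- .stratifiedFolds(labels, nFolds, seed)
  alphas <- c(0.01, seq(0.1, 1, by = 0.1))
  best <- NULL
  bestErr <- Inf
  path <- list()
  for (a in alphas) {
    cvfit <- .cvGlmnetAt(enc@X, y, alpha = a, foldid = foldid)
    path[[length(path) + 1]] <-
      data.frame(alpha = a, lambda = cvfit$lambda, error = cvfit$cvm)
    err <- min(cvfit$cvm)
    if (err <= bestErr) {  # ascending grid: later (larger) alpha wins ties
      bestErr <- err
      best <- list(cvfit = cvfit, alpha = a)
    }
  }
  .penalizedFromCv(best$cvfit, best$alpha, "enet", enc, classLevels,
                   do.call(rbind, path))
}

#' @rdname predictProba
setMethod("predictProba", "PenalizedModel", function(object, newdata, ...) {
  enc <- encodeWithScheme(object@encoding, newdata)
  pr <- predict(object@fit, newx = enc@X, s = object@lambda,
                type = "response")
  pr <- pr[, , 1, drop = TRUE]
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1,
                                     dimnames = list(rownames(enc@X),
                                                     names(pr)))
  pr <- pr[, object@classLevels, drop = FALSE]
  rownames(pr) <- rownames(enc@X)
  pr
})
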