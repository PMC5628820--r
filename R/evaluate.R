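# Confusion-matrix evaluation, feature harmonization across cohorts, and
# cross-cohort validation (train on one cohort, test on the other).

.evalFromProba <- function(proba, truth, classLevels) {
  # argmax prediction; ties resolved by the sorted class order (first max)
  pred <- classLevels[apply(proba, 1, which.max)]
  truthF <- factor(truth, levels = classLevels)
  predF <- factor(pred, levels = classLevels)
  confusion <- unclass(table(truth = truthF, prediction = predF))
  n <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- n - tp - fn - fp
  new("EvalReport", confusion = confusion,
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      accuracy = sum(tp) / n)
}

.evaluateCommon <- function(object, newdata) {
  if (length(sampleIds(newdata)) == 0) stop("empty test set")
  truth <- phenoLabels(newdata)
  if (is.null(truth)) stop("test data must be labeled")
  proba <- predictProba(object, newdata)
  .evalFromProba(proba, truth, object@classLevels)
}

#' @rdname evaluateModel
setMethod("evaluateModel", "PenalizedModel", .evaluateCommon)

#' @rdname evaluateModel
setMethod("evaluateModel", "ForestModel", .evaluateCommon)

#' Restrict two cohorts to their shared features
#'
#' @param a,b preprocessed [PhenotypeSet-class] objects.
#' @return `list(a, b, shared)`: both sets restricted to the intersection of
#'   their feature ids, in `a`'s order.
#' @export
harmonizeFeatures <- function(a, b) {
  shared <- intersect(featureIds(a), featureIds(b))
  if (length(shared) == 0) stop("no shared features between the cohorts")
  list(a = PhenotypeSet(traitMatrix(a)[, shared, drop = FALSE],
                        labels = phenoLabels(a)),
       b = PhenotypeSet(traitMatrix(b)[, shared, drop = FALSE],
                        labels = phenoLabels(b)),
       shared = shared)
}

#' Train on one cohort, validate on another
#'
#' Harmonizes the two cohorts to their shared features, retrains the chosen
#' method on a stratified 90% of cohort `a`, and evaluates on all of cohort
#' `b`.  Calling with the cohorts swapped gives the reverse validation.
#'
#' @param a training cohort (labeled, preprocessed [PhenotypeSet-class]).
#' @param b validation cohort.
#' @param method one of `"lasso"`, `"enet"`, `"rf"`.
#' @param seed RNG seed (split, folds, forests).
#' @param trainFraction fraction of `a` used for training (default 0.9).
#' @param ... extra arguments for the fitting function.
#' @return `list(model, report, shared)` with the fitted model, the
#'   [EvalReport-class] on `b`, and the shared feature ids.
#' @export
crossCohortValidate <- function(a, b, method = c("lasso", "enet", "rf"),
                                seed = 1L, trainFraction = 0.9, ...) {
  method <- match.arg(method)
  h <- harmonizeFeatures(a, b)
  split <- splitTrainTest(h$a, fraction = trainFraction, seed = seed)
  model <- switch(method,
    lasso = fitLasso(split$train, seed = seed, ...),
    enet = fitEnet(split$train, seed = seed, ...),
    rf = fitForest(split$train, seed = seed, ...))
  list(model = model, report = evaluateModel(model, h$b), shared = h$shared)
}
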