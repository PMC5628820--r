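#' Predicted class-membership probabilities
#'
#' Probabilities are non-negative and sum to one per sample: softmax over
#' linear predictors for penalized models, tree-vote fractions for forests.
#' An error names any feature the model requires that `newdata` lacks.
#'
#' @param object a fitted [PenalizedModel-class] or [ForestModel-class].
#' @param newdata a [PhenotypeSet-class].
#' @param ... unused.
#' @return samples-by-classes numeric matrix of probabilities.
#' @export
setGeneric("predictProba", function(object, newdata, ...)
  standardGeneric("predictProba"))

#' Evaluate a classifier on a labeled PhenotypeSet
#'
#' Predicts by the maximum-probability class (ties broken by the model's
#' sorted class order) and tabulates a confusion matrix with one-vs-rest
#' sensitivity and specificity per class.
#'
#' @param object a fitted classifier.
#' @param newdata a labeled [PhenotypeSet-class].
#' @param ... unused.
#' @return an [EvalReport-class].
#' @export
setGeneric("evaluateModel", function(object, newdata, ...)
  standardGeneric("evaluateModel"))

#' Features retained by a fitted model or selection procedure
#' @param object a fitted model or [BorutaResult-class].
#' @return character vector of feature ids.
#' @export
setGeneric("selectedFeatures", function(object)
  standardGeneric("selectedFeatures"))

#' @rdname selectedFeatures
setMethod("selectedFeatures", "PenalizedModel",
          function(object) object@selectedFeatures)

#' @rdname selectedFeatures
setMethod("selectedFeatures", "ForestModel", function(object) object@features)

#' @rdname selectedFeatures
setMethod("selectedFeatures", "BorutaResult", function(object) object@confirmed)
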