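#' @import methods
#' @importFrom stats runif rgamma sd median quantile rnorm setNames plogis
#'   binom.test chisq.test predict coef cmdscale
#' @importFrom utils head tail read.delim write.table packageVersion
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

# ---------------------------------------------------------------------------
# PhenotypeSet: categorical trait matrix with optional constitution labels
# ---------------------------------------------------------------------------

#' PhenotypeSet: samples-by-traits categorical phenotype container
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding one
#' character assay `"traits"` (features in rows, samples in columns, matching
#' the Bioconductor convention) and an optional per-sample class label in
#' `colData(x)$label`.  Labels are either extreme constitution types
#' (e.g. `"V"`, `"P"`, `"K"`) or mixture codes (e.g. `"VP"`).  Missing
#' responses are `NA`.
#'
#' @export
setClass("PhenotypeSet", contains = "SummarizedExperiment")

setValidity("PhenotypeSet", function(object) {
  if (!"traits" %in% SummarizedExperiment::assayNames(object))
    return("assay 'traits' is required")
  a <- SummarizedExperiment::assay(object, "traits")
  if (!is.character(a))
    return("assay 'traits' must be a character matrix")
  if ((nrow(a) > 0 && is.null(rownames(a))) ||
      (ncol(a) > 0 && is.null(colnames(a))))
    return("assay 'traits' must have feature and sample names")
  if (anyDuplicated(rownames(a))) return("feature ids must be unique")
  if (anyDuplicated(colnames(a))) return("sample ids must be unique")
  if ("label" %in% colnames(colData(object)) &&
      !is.character(colData(object)$label))
    return("colData 'label' must be character")
  TRUE
})

#' Construct a PhenotypeSet from a samples-by-features table
#'
#' @param traits data.frame or matrix, samples in rows, categorical features in
#'   columns; values are coerced to character.  Row names (or `sampleIds`)
#'   identify samples.
#' @param labels optional character vector of per-sample class labels.
#' @param sampleIds,featureIds identifiers; default to dimnames of `traits`.
#' @return A [PhenotypeSet-class] object.
#' @examples
#' ps <- PhenotypeSet(data.frame(q1 = c("a", "b"), q2 = c("a", "a"),
#'                               row.names = c("s1", "s2")),
#'                    labels = c("V", "K"))
#' @export
PhenotypeSet <- function(traits, labels = NULL,
                         sampleIds = rownames(traits),
                         featureIds = colnames(traits)) {
  if (is.data.frame(traits)) {
    rn <- rownames(traits)
    traits <- as.matrix(as.data.frame(lapply(traits, as.character),
                                      optional = TRUE))
    rownames(traits) <- rn
  }
  traits <- as.matrix(traits)
  storage.mode(traits) <- "character"
  if (is.null(sampleIds)) sampleIds <- sprintf("S%03d", seq_len(nrow(traits)))
  if (is.null(featureIds)) featureIds <- sprintf("Q%03d", seq_len(ncol(traits)))
  dimnames(traits) <- list(sampleIds, featureIds)
  cd <- if (is.null(labels)) DataFrame(row.names = sampleIds)
        else DataFrame(label = as.character(labels), row.names = sampleIds)
  se <- SummarizedExperiment(assays = list(traits = t(traits)), colData = cd)
  new("PhenotypeSet", se)
}

#' @describeIn PhenotypeSet sample identifiers (assay columns).
#' @param x a PhenotypeSet.
#' @export
sampleIds <- function(x) colnames(SummarizedExperiment::assay(x, "traits"))

#' @describeIn PhenotypeSet feature identifiers (assay rows).
#' @export
featureIds <- function(x) rownames(SummarizedExperiment::assay(x, "traits"))

#' @describeIn PhenotypeSet per-sample class labels, or `NULL` when absent.
#' @export
phenoLabels <- function(x) {
  cd <- colData(x)
  if ("label" %in% colnames(cd)) as.character(cd$label) else NULL
}

#' @describeIn PhenotypeSet samples-by-features character matrix.
#' @export
traitMatrix <- function(x) t(SummarizedExperiment::assay(x, "traits"))

#' @describeIn PhenotypeSet samples-by-features data.frame of factors, each
#'   feature with its sorted observed level set; the input to all models.
#' @export
traitTable <- function(x) {
  m <- traitMatrix(x)
  out <- as.data.frame(m, stringsAsFactors = FALSE, optional = TRUE)
  out[] <- lapply(out, function(v) factor(v, levels = sort(unique(v[!is.na(v)]))))
  out
}

setMethod("show", "PhenotypeSet", function(object) {
  m <- SummarizedExperiment::assay(object, "traits")
  cat("PhenotypeSet:", ncol(m), "samples x", nrow(m), "features\n")
  lab <- phenoLabels(object)
  if (!is.null(lab)) {
    tb <- table(lab)
    cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(m))))
})

# ---------------------------------------------------------------------------
# CohortSpec: generative model parameters for synthetic questionnaire cohorts
# ---------------------------------------------------------------------------

#' CohortSpec: parameters of the synthetic questionnaire-cohort generator
#'
#' Describes a latent-class generative model for categorical questionnaire
#' data: `nInformative` class-informative features (each class concentrates
#' probability `signalStrength` on its preferred level), contiguous correlated
#' feature blocks coupled through a shared per-sample latent draw, a pool of
#' non-informative features sharing one multinomial, non-extreme samples that
#' mix two parent classes feature-wise, and MCAR missingness.
#'
#' @slot classNames names of the extreme classes (default `V`, `P`, `K`).
#' @slot nPerClass integer count of extreme samples per class.
#' @slot nNonExtreme named integer counts of mixture samples per class pair
#'   (names such as `"VP"`).
#' @slot nFeatures,nInformative total and class-informative feature counts;
#'   informative features occupy positions 1..nInformative.
#' @slot levelsPerFeature integer in 2..4 per feature.
#' @slot signalStrength probability mass on a class's preferred level for
#'   informative features (values at or below the uniform baseline 1/L make
#'   the feature uninformative).
#' @slot nBlocks number of contiguous correlated feature blocks.
#' @slot blockCoupling probability an informative feature reuses its block's
#'   per-sample latent draw rather than an independent one.
#' @slot missingRate MCAR missingness rate in [0, 0.2].
#' @slot seed integer master seed; spec plus seed fully determines a cohort.
#' @export
setClass("CohortSpec", representation(
  classNames = "character", nPerClass = "integer", nNonExtreme = "integer",
  nFeatures = "integer", nInformative = "integer",
  levelsPerFeature = "integer", signalStrength = "numeric",
  nBlocks = "integer", blockCoupling = "numeric", missingRate = "numeric",
  seed = "integer"))

setValidity("CohortSpec", function(object) {
  bad <- function(field, why) sprintf("invalid '%s': %s", field, why)
  if (length(object@classNames) < 2 || anyDuplicated(object@classNames))
    return(bad("classNames", "need >= 2 unique class names"))
  if (length(object@nPerClass) != length(object@classNames) ||
      any(object@nPerClass < 0))
    return(bad("nPerClass", "one non-negative count per class"))
  if (any(object@nNonExtreme < 0))
    return(bad("nNonExtreme", "counts must be non-negative"))
  if (object@nFeatures < 1) return(bad("nFeatures", "must be >= 1"))
  if (object@nInformative < 0 || object@nInformative > object@nFeatures)
    return(bad("nInformative", "must be in [0, nFeatures]"))
  if (length(object@levelsPerFeature) != object@nFeatures ||
      any(object@levelsPerFeature < 2) || any(object@levelsPerFeature > 4))
    return(bad("levelsPerFeature", "one integer in [2,4] per feature"))
  if (object@signalStrength < 0 || object@signalStrength > 1)
    return(bad("signalStrength", "must be in [0,1]"))
  if (object@nBlocks < 1 || object@nBlocks > object@nFeatures)
    return(bad("nBlocks", "must be in [1, nFeatures]"))
  if (object@blockCoupling < 0 || object@blockCoupling > 1)
    return(bad("blockCoupling", "must be in [0,1]"))
  if (object@missingRate < 0 || object@missingRate > 0.2)
    return(bad("missingRate", "must be in [0,0.2]"))
  if (length(object@seed) != 1 || is.na(object@seed))
    return(bad("seed", "must be a single integer"))
  TRUE
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", sum(object@nPerClass), "extreme (",
      paste(sprintf("%s=%d", object@classNames, object@nPerClass),
            collapse = " "), "),",
      sum(object@nNonExtreme), "non-extreme;",
      object@nFeatures, "features (", object@nInformative, "informative,",
      object@nBlocks, "blocks )\n")
  cat(sprintf("  signal=%.2f coupling=%.2f missing=%.2f seed=%d\n",
              object@signalStrength, object@blockCoupling,
              object@missingRate, object@seed))
})

# ---------------------------------------------------------------------------
# PreprocessReport
# ---------------------------------------------------------------------------

#' PreprocessReport: audit trail of the cleaning pipeline
#'
#' @slot removedMissing features removed for > threshold missingness.
#' @slot removedNonVarying features removed as constant after imputation.
#' @slot imputed data.frame (feature, mode, nImputed) of mode imputations.
#' @slot nFeaturesIn,nFeaturesOut feature counts before and after cleaning.
#' @export
setClass("PreprocessReport", representation(
  removedMissing = "character", removedNonVarying = "character",
  imputed = "data.frame", nFeaturesIn = "integer", nFeaturesOut = "integer"))

setMethod("show", "PreprocessReport", function(object) {
  cat("PreprocessReport:", object@nFeaturesIn, "->", object@nFeaturesOut,
      "features\n")
  cat("  removed (missingness):", length(object@removedMissing),
      "| removed (non-varying):", length(object@removedNonVarying),
      "| imputed cells:", sum(object@imputed$nImputed), "\n")
})

# ---------------------------------------------------------------------------
# DissimilarityMatrix
# ---------------------------------------------------------------------------

#' DissimilarityMatrix: pairwise sample dissimilarity (1 - RF proximity)
#'
#' @slot d symmetric numeric matrix in [0,1] with zero diagonal; dimnames are
#'   sample ids.
#' @slot ntree,seed forest size and seed used to derive it (NA when built
#'   directly from a matrix).
#' @export
setClass("DissimilarityMatrix", representation(
  d = "matrix", ntree = "integer", seed = "integer"))

setValidity("DissimilarityMatrix", function(object) {
  d <- object@d
  if (nrow(d) != ncol(d)) return("matrix must be square")
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
    return("dimnames must be identical sample ids")
  if (anyDuplicated(rownames(d))) return("sample ids must be unique")
  if (max(abs(d - t(d))) > 1e-8) return("matrix must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) return("diagonal must be zero")
  if (min(d) < -1e-12 || max(d) > 1 + 1e-12)
    return("entries must lie in [0,1]")
  TRUE
})

#' Wrap a plain symmetric matrix as a DissimilarityMatrix
#' @param d symmetric numeric matrix in [0,1], zero diagonal, dimnames = ids.
#' @param ntree,seed provenance (optional).
#' @export
DissimilarityMatrix <- function(d, ntree = NA_integer_, seed = NA_integer_) {
  d <- as.matrix(d)
  if (is.null(rownames(d)))
    dimnames(d) <- list(sprintf("S%03d", seq_len(nrow(d))),
                        sprintf("S%03d", seq_len(nrow(d))))
  new("DissimilarityMatrix", d = d, ntree = as.integer(ntree),
      seed = as.integer(seed))
}

#' @describeIn DissimilarityMatrix the underlying numeric matrix.
#' @param x a DissimilarityMatrix.
#' @export
dissMatrix <- function(x) x@d

setMethod("show", "DissimilarityMatrix", function(object) {
  cat("DissimilarityMatrix:", nrow(object@d), "samples",
      if (!is.na(object@ntree)) sprintf("(ntree=%d)", object@ntree), "\n")
  cat(sprintf("  range [%.3f, %.3f], mean %.3f\n",
              min(object@d), max(object@d),
              mean(object@d[upper.tri(object@d)])))
})

# ---------------------------------------------------------------------------
# ClusterSolution & SavannahResult
# ---------------------------------------------------------------------------

#' ClusterSolution: one PAM partition
#'
#' @slot k number of clusters.
#' @slot medoids sample ids of the medoids.
#' @slot assignment integer cluster index per sample (named); every sample is
#'   assigned to its nearest medoid, ties to the lowest medoid index.
#' @slot silWidths per-sample silhouette widths (0 for members of singleton
#'   clusters; NA when k = 1).
#' @slot avgSilWidth mean silhouette width.
#' @slot cost total dissimilarity of samples to their medoids.
#' @export
setClass("ClusterSolution", representation(
  k = "integer", medoids = "character", assignment = "integer",
  silWidths = "numeric", avgSilWidth = "numeric", cost = "numeric"))

setMethod("show", "ClusterSolution", function(object) {
  cat("ClusterSolution: k =", object@k,
      sprintf("| avg silhouette = %.3f | cost = %.3f\n",
              object@avgSilWidth, object@cost))
  print(table(cluster = object@assignment))
})

#' SavannahResult: silhouette widths of original vs column-permuted data
#'
#' @slot kGrid cluster numbers evaluated.
#' @slot originalWidths average silhouette width per k on the original data.
#' @slot permutedWidths replicate-by-k matrix of widths on permuted data.
#' @slot nPermutations,ntree,seed run parameters.
#' @export
setClass("SavannahResult", representation(
  kGrid = "integer", originalWidths = "numeric", permutedWidths = "matrix",
  nPermutations = "integer", ntree = "integer", seed = "integer"))

setValidity("SavannahResult", function(object) {
  if (length(object@originalWidths) != length(object@kGrid))
    return("originalWidths must align with kGrid")
  if (ncol(object@permutedWidths) != length(object@kGrid) ||
      nrow(object@permutedWidths) != object@nPermutations)
    return("permutedWidths must be nPermutations x length(kGrid)")
  TRUE
})

setMethod("show", "SavannahResult", function(object) {
  kstar <- object@kGrid[which.max(object@originalWidths)]
  cat("SavannahResult:", object@nPermutations, "permutations, k in [",
      min(object@kGrid), ",", max(object@kGrid), "]\n")
  cat(sprintf("  original optimum: k=%d width=%.3f | permuted max width=%.3f\n",
              kstar, max(object@originalWidths), max(object@permutedWidths)))
})

# ---------------------------------------------------------------------------
# EncodedDesign
# ---------------------------------------------------------------------------

#' EncodedDesign: 0/1 dummy coding of a categorical trait table
#'
#' One indicator column per non-reference level per feature; the reference
#' level is the feature's most frequent level (ties broken lexicographically).
#'
#' @slot X samples-by-columns 0/1 matrix; column names `feature=level`.
#' @slot parent named map column -> feature id.
#' @slot encoding per-feature list with elements `levels` and `ref`, used to
#'   encode new data consistently (unseen levels score as the reference).
#' @export
setClass("EncodedDesign", representation(
  X = "matrix", parent = "character", encoding = "list"))

setMethod("show", "EncodedDesign", function(object) {
  cat("EncodedDesign:", nrow(object@X), "samples x", ncol(object@X),
      "indicator columns (", length(object@encoding), "features )\n")
})

# ---------------------------------------------------------------------------
# Fitted classifiers
# ---------------------------------------------------------------------------

#' PenalizedModel: multinomial LASSO or elastic-net classifier
#'
#' @slot method `"lasso"` or `"enet"`.
#' @slot alpha mixing parameter (1 for LASSO).
#' @slot lambda selected penalty strength.
#' @slot fit the underlying `glmnet` fit on the full training data.
#' @slot encoding dummy-coding scheme of the training data (see
#'   [EncodedDesign-class]).
#' @slot classLevels class labels in the model's (sorted) order.
#' @slot selectedFeatures parents of any nonzero coefficient in any class.
#' @slot cvPath data.frame (alpha, lambda, error) of cross-validation records.
#' @export
setClass("PenalizedModel", representation(
  method = "character", alpha = "numeric", lambda = "numeric", fit = "ANY",
  encoding = "list", classLevels = "character",
  selectedFeatures = "character", cvPath = "data.frame"))

setMethod("show", "PenalizedModel", function(object) {
  cat(sprintf("PenalizedModel (%s): alpha=%.2f lambda=%.4g | %d features selected\n",
              object@method, object@alpha, object@lambda,
              length(object@selectedFeatures)))
})

#' ForestModel: tuned random-forest classifier on Boruta-confirmed features
#'
#' @slot ntree,mtry tuned hyperparameters.
#' @slot features the feature set the forest was grown on.
#' @slot levelsMap per-feature training levels and modal level (used to align
#'   new data; unseen levels fall back to the training mode).
#' @slot classLevels class labels in the model's order.
#' @slot forest the fitted `randomForest` object.
#' @slot oobError out-of-bag misclassification rate of the final forest.
#' @slot tuning data.frame of the tuning grid (stage, value, medianOOB, sdOOB).
#' @export
setClass("ForestModel", representation(
  ntree = "integer", mtry = "integer", features = "character",
  levelsMap = "list", classLevels = "character", forest = "ANY",
  oobError = "numeric", tuning = "data.frame"))

setMethod("show", "ForestModel", function(object) {
  cat(sprintf("ForestModel: ntree=%d mtry=%d | %d features | OOB error %.3f\n",
              object@ntree, object@mtry, length(object@features),
              object@oobError))
})

#' BorutaResult: shadow-feature selection outcome
#'
#' @slot confirmed,rejected,tentative feature id sets after resolution
#'   (`tentative` holds features that required the median-importance
#'   resolution step, all of which end in `confirmed` or `rejected`).
#' @slot nRuns number of shadow runs performed.
#' @slot hits named hit counts per feature at its decision time.
#' @slot impMedian median permutation importance per feature across runs.
#' @slot shadowMedian median of the per-run shadow importance maxima.
#' @export
setClass("BorutaResult", representation(
  confirmed = "character", rejected = "character", tentative = "character",
  nRuns = "integer", hits = "numeric", impMedian = "numeric",
  shadowMedian = "numeric"))

setMethod("show", "BorutaResult", function(object) {
  cat("BorutaResult:", length(object@confirmed), "confirmed,",
      length(object@rejected), "rejected (",
      length(object@tentative), "resolved from tentative ) in",
      object@nRuns, "runs\n")
})

# ---------------------------------------------------------------------------
# Evaluation containers
# ---------------------------------------------------------------------------

#' EvalReport: confusion matrix with one-vs-rest sensitivity/specificity
#'
#' @slot confusion class-by-class counts, rows = truth, columns = prediction.
#' @slot sensitivity,specificity per-class one-vs-rest proportions.
#' @slot accuracy overall accuracy, trace(confusion)/n.
#' @export
setClass("EvalReport", representation(
  confusion = "matrix", sensitivity = "numeric", specificity = "numeric",
  accuracy = "numeric"))

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: accuracy %.1f%%\n", 100 * object@accuracy))
  print(object@confusion)
  tab <- rbind(`sensitivity (%)` = round(100 * object@sensitivity, 2),
               `specificity (%)` = round(100 * object@specificity, 2))
  print(tab)
})

#' MaximaScores: per-sample maxima of class-membership probabilities
#'
#' @slot sampleIds sample identifiers.
#' @slot score max class probability per sample, in [1/K, 1].
#' @slot sourceMethod `"lasso"`, `"enet"` or `"rf"`.
#' @slot isExtreme logical truth (TRUE = extreme class), NA when unknown.
#' @export
setClass("MaximaScores", representation(
  sampleIds = "character", score = "numeric", sourceMethod = "character",
  isExtreme = "logical"))

setValidity("MaximaScores", function(object) {
  if (length(object@score) != length(object@sampleIds))
    return("score and sampleIds must align")
  if (any(object@score < 0 - 1e-12 | object@score > 1 + 1e-12))
    return("scores must lie in [0,1]")
  TRUE
})

setMethod("show", "MaximaScores", function(object) {
  cat("MaximaScores (", object@sourceMethod, "):",
      length(object@score), "samples\n")
  if (!all(is.na(object@isExtreme))) {
    cat(sprintf("  median score: extreme %.3f | non-extreme %.3f\n",
                median(object@score[object@isExtreme %in% TRUE]),
                median(object@score[object@isExtreme %in% FALSE])))
  }
})

#' BinaryModel: logistic extreme-vs-non-extreme classifier on maxima scores
#'
#' @slot intercept,slope coefficients of the scalar logistic model.
#' @slot threshold posterior classification threshold.
#' @slot cvAccuracies stratified 10-fold cross-validation accuracies.
#' @slot cvPredictions out-of-fold posterior per sample (named).
#' @slot auc Mann-Whitney AUC of the raw scores.
#' @slot separated TRUE when perfect separation forced the ridge fallback.
#' @slot sourceMethod base classifier the scores came from.
#' @export
setClass("BinaryModel", representation(
  intercept = "numeric", slope = "numeric", threshold = "numeric",
  cvAccuracies = "numeric", cvPredictions = "numeric", auc = "numeric",
  separated = "logical", sourceMethod = "character"))

setMethod("show", "BinaryModel", function(object) {
  cat(sprintf("BinaryModel (%s): logit(p) = %.3f + %.3f * score%s\n",
              object@sourceMethod, object@intercept, object@slope,
              if (object@separated) "  [ridge: separated]" else ""))
  cat(sprintf("  mean CV accuracy %.3f | AUC %.3f\n",
              mean(object@cvAccuracies), object@auc))
})
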