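# Cleaning of raw categorical questionnaire tables:
# (1) drop features with strictly more than `threshold` missing values,
# (2) impute remaining missing cells with the feature's mode,
# (3) drop features left non-varying.
# The order matters: a feature made constant by imputation is removed.

.featureMode <- function(v) {
  tb <- table(v[!is.na(v)])
  if (length(tb) == 0) stop("feature has no observed values")
  # ties broken by lexicographic level order (table() sorts its names)
  names(tb)[which.max(tb)]
}

#' Remove features with excessive missingness
#'
#' A feature is removed iff its missing fraction strictly exceeds
#' `threshold`; a feature at exactly the threshold is retained.
#'
#' @param pset a [PhenotypeSet-class].
#' @param threshold missing-fraction cutoff in [0, 1] (default 0.05).
#' @return `list(data = PhenotypeSet, removed = character)`.
#' @export
filterMissing <- function(pset, threshold = 0.05) {
  if (threshold < 0 || threshold > 1) stop("'threshold' must lie in [0,1]")
  m <- traitMatrix(pset)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty phenotype matrix")
  frac <- colMeans(is.na(m))
  removed <- colnames(m)[frac > threshold]
  keep <- setdiff(colnames(m), removed)
  list(data = PhenotypeSet(m[, keep, drop = FALSE],
                           labels = phenoLabels(pset)),
       removed = removed)
}

#' Impute missing cells with the feature mode
#'
#' Every missing cell is replaced by its feature's most frequent observed
#' level; ties are broken by lexicographic level order.
#'
#' @param pset a [PhenotypeSet-class]; every feature must have at least one
#'   observed value.
#' @return `list(data = PhenotypeSet, imputed = data.frame)` where `imputed`
#'   has one row (feature, mode, nImputed) per feature that had missing cells.
#' @export
imputeMode <- function(pset) {
  m <- traitMatrix(pset)
  nmiss <- colSums(is.na(m))
  rows <- list()
  for (j in which(nmiss > 0)) {
    if (nmiss[j] == nrow(m))
      stop("feature '", colnames(m)[j],
           "' is entirely missing; filter it before imputation")
    mode <- .featureMode(m[, j])
    m[is.na(m[, j]), j] <- mode
    rows[[length(rows) + 1]] <-
      data.frame(feature = colnames(m)[j], mode = mode,
                 nImputed = as.integer(nmiss[j]), stringsAsFactors = FALSE)
  }
  imputed <- if (length(rows)) do.call(rbind, rows)
             else data.frame(feature = character(), mode = character(),
                             nImputed = integer())
  list(data = PhenotypeSet(m, labels = phenoLabels(pset)), imputed = imputed)
}

#' Remove non-varying features
#'
#' Features whose observed values are all a single level carry no
#' information and are dropped.
#'
#' @param pset a [PhenotypeSet-class] (normally already imputed).
#' @return `list(data = PhenotypeSet, removed = character)`.
#' @export
dropNonVarying <- function(pset) {
  m <- traitMatrix(pset)
  nlev <- apply(m, 2, function(v) length(unique(v[!is.na(v)])))
  removed <- colnames(m)[nlev <= 1]
  keep <- setdiff(colnames(m), removed)
  list(data = PhenotypeSet(m[, keep, drop = FALSE],
                           labels = phenoLabels(pset)),
       removed = removed)
}

#' Full preprocessing pipeline: filter, impute, drop
#'
#' Applies [filterMissing()], [imputeMode()] and [dropNonVarying()] in that
#' order and returns the cleaned data with a [PreprocessReport-class].
#' The pipeline is idempotent and preserves the input feature order among
#' retained features; its output has no missing values and no constant
#' features.
#'
#' @param pset a [PhenotypeSet-class].
#' @param threshold missingness cutoff passed to [filterMissing()].
#' @return `list(data = PhenotypeSet, report = PreprocessReport)`.
#' @export
preprocessPhenotypes <- function(pset, threshold = 0.05) {
  nIn <- length(featureIds(pset))
  f <- filterMissing(pset, threshold)
  i <- imputeMode(f$data)
  d <- dropNonVarying(i$data)
  report <- new("PreprocessReport",
                removedMissing = f$removed, removedNonVarying = d$removed,
                imputed = i$imputed, nFeaturesIn = as.integer(nIn),
                nFeaturesOut = length(featureIds(d$data)))
  list(data = d$data, report = report)
}
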