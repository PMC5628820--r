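#' Stratified train/test split
#'
#' Draws a class-stratified random split.  The test size of each class is
#' `(1 - fraction) * classSize` rounded to the nearest integer (halves
#' upward), which on the 66/35/46 three-class cohort with `fraction = 0.9`
#' yields the canonical 16-sample hold-out of 7/4/5.
#'
#' @param pset a labeled [PhenotypeSet-class].
#' @param fraction training fraction in (0, 1]; `fraction = 1` gives an empty
#'   test set.
#' @param seed RNG seed.
#' @return `list(train = PhenotypeSet, test = PhenotypeSet)`.
#' @export
splitTrainTest <- function(pset, fraction = 0.9, seed = 1L) {
  labels <- phenoLabels(pset)
  if (is.null(labels)) stop("labels required for a stratified split")
  if (fraction <= 0 || fraction > 1) stop("'fraction' must lie in (0, 1]")
  counts <- table(labels)
  if (any(counts < 2)) stop("every class needs at least 2 samples")
  set.seed(seed)
  testIdx <- integer(0)
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    # nearest integer with halves up; the epsilon guards against binary
    # representation error in (1 - fraction) * n (e.g. 0.1 * 35)
    nTest <- min(floor((1 - fraction) * length(idx) + 0.5 + 1e-9),
                 length(idx) - 1L)
    if (nTest > 0) testIdx <- c(testIdx, sample(idx, nTest))
  }
  testIdx <- sort(testIdx)
  trainIdx <- setdiff(seq_along(labels), testIdx)
  m <- traitMatrix(pset)
  list(train = PhenotypeSet(m[trainIdx, , drop = FALSE],
                            labels = labels[trainIdx]),
       test = PhenotypeSet(m[testIdx, , drop = FALSE],
                           labels = labels[testIdx]))
}

# stratified fold ids 1..k, balanced within class
.stratifiedFolds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}
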