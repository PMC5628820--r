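# Unsupervised random-forest dissimilarity.  A two-class forest separates the
# real samples from a synthetic contrast class whose columns are independent
# permutations of the originals (marginals preserved, joint structure
# destroyed).  Proximity between two real samples is the fraction of trees in
# which they share a terminal node; the dissimilarity is 1 - proximity.

#' Column-permuted synthetic contrast data
#'
#' Returns a matrix of the same shape in which each column is an independent
#' permutation (sampling without replacement) of the corresponding original
#' column: per-feature level counts are preserved exactly while all joint
#' structure between features is destroyed.
#'
#' @param pset a [PhenotypeSet-class] without missing values.
#' @param seed RNG seed.
#' @return an unlabeled [PhenotypeSet-class].
#' @export
syntheticContrast <- function(pset, seed = 1L) {
  m <- traitMatrix(pset)
  if (anyNA(m)) stop("missing values present; preprocess first")
  set.seed(seed)
  perm <- apply(m, 2, sample)
  dimnames(perm) <- dimnames(m)
  PhenotypeSet(perm)
}

#' Random-forest proximity dissimilarity (unsupervised mode)
#'
#' Labels the original samples as one class and a [syntheticContrast()] of the
#' same size as the other, grows `ntree` classification trees
#' (via \pkg{randomForest}), and returns `1 - proximity` restricted to the
#' original samples.  By default proximity is counted over all trees; set
#' `oobProx = TRUE` to count only trees where both samples are out-of-bag.
#'
#' @param pset a preprocessed [PhenotypeSet-class] (no missing values, no
#'   constant features).
#' @param ntree number of trees (default 10000).
#' @param mtry features tried per split; default `floor(sqrt(p))`.
#' @param seed RNG seed (controls both the contrast permutation and the
#'   forest).
#' @param oobProx restrict proximity counting to jointly out-of-bag trees.
#' @return a [DissimilarityMatrix-class].
#' @export
rfDissimilarity <- function(pset, ntree = 10000L, mtry = NULL, seed = 1L,
                            oobProx = FALSE) {
  if (ntree < 1) stop("'ntree' must be >= 1")
  x <- traitTable(pset)
  n <- nrow(x)
  if (n < 2) stop("need at least two samples")
  if (anyNA(traitMatrix(pset))) stop("missing values present; preprocess first")
  contrast <- traitTable(syntheticContrast(pset, seed = seed))
  xx <- rbind(x, contrast)
  rownames(xx) <- c(rownames(x), paste0("synth_", rownames(x)))
  y <- factor(rep(c("original", "synthetic"), each = n))
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  rf <- randomForest::randomForest(
    x = xx, y = y, ntree = as.integer(ntree), mtry = as.integer(mtry),
    proximity = TRUE, oob.prox = oobProx, keep.forest = FALSE)
  prox <- rf$proximity[seq_len(n), seq_len(n)]
  d <- 1 - (prox + t(prox)) / 2
  d[d < 0] <- 0
  d[d > 1] <- 1
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  new("DissimilarityMatrix", d = d, ntree = as.integer(ntree),
      seed = as.integer(seed))
}
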