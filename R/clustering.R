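# PAM clustering on the forest dissimilarity, silhouette-based selection of
# the number of clusters, the column-permutation ("Savannah") null, optimal
# cluster-to-label agreement and classical MDS coordinates.

.nearestMedoidAssignment <- function(d, medoidIdx) {
  # ties resolved to the lowest medoid index (which.min is first-wins)
  apply(d[, medoidIdx, drop = FALSE], 1, which.min)
}

#' Partition around medoids on a dissimilarity matrix
#'
#' k-medoid clustering minimizing the total dissimilarity of samples to
#' their nearest medoid.  Instances whose medoid-set space is small
#' (`choose(n, k) <= 3000`) are solved exactly by deterministic exhaustive
#' enumeration (first lexicographic optimum on ties); larger instances use
#' classic PAM BUILD + SWAP via \pkg{cluster}: BUILD greedily selects `k`
#' medoids, SWAP applies strictly cost-decreasing medoid/non-medoid
#' exchanges until none remains.  The returned assignment maps every sample
#' to its nearest medoid, ties to the lowest medoid index.  `k = 1` returns
#' the sample minimizing total dissimilarity; `k = n` makes every sample its
#' own medoid at zero cost.
#'
#' @param D a [DissimilarityMatrix-class].
#' @param k number of clusters, 1..n.
#' @return a [ClusterSolution-class].
#' @export
pamClustering <- function(D, k) {
  d <- dissMatrix(D)
  n <- nrow(d)
  if (k < 1 || k > n) stop("'k' must lie in [1, n]")
  ids <- rownames(d)
  if (k == n) {
    medoidIdx <- seq_len(n)
  } else if (k == 1) {
    medoidIdx <- which.min(colSums(d))
  } else if (choose(n, k) <= 3000) {
    # exact solution where affordable: BUILD+SWAP is a local search and can
    # miss the optimum on small awkward instances
    best <- Inf
    medoidIdx <- seq_len(k)
    for (med in asplit(utils::combn(n, k), 2)) {
      cost <- sum(apply(d[, med, drop = FALSE], 1, min))
      if (cost < best) {
        best <- cost
        medoidIdx <- med
      }
    }
  } else {
    fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE,
                        keep.diss = FALSE, keep.data = FALSE)
    medoidIdx <- match(fit$medoids, ids)
  }
  assignment <- .nearestMedoidAssignment(d, medoidIdx)
  cost <- sum(d[cbind(seq_len(n), medoidIdx[assignment])])
  if (k >= 2 && k < n) {
    sil <- silhouetteWidths(D, assignment)
  } else if (k == n) {
    sil <- list(widths = setNames(rep(0, n), ids), avg = 0)
  } else {
    sil <- list(widths = setNames(rep(NA_real_, n), ids), avg = NA_real_)
  }
  new("ClusterSolution", k = as.integer(k), medoids = ids[medoidIdx],
      assignment = setNames(as.integer(assignment), ids),
      silWidths = sil$widths, avgSilWidth = sil$avg, cost = cost)
}

#' Silhouette widths of a partition
#'
#' For sample i with own-cluster mean dissimilarity `a(i)` (excluding self)
#' and `b(i)` the smallest mean dissimilarity to any other cluster,
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`.  Members of singleton clusters
#' get `s(i) = 0` by convention.
#'
#' @param D a [DissimilarityMatrix-class].
#' @param assignment integer cluster index per sample; at least two
#'   non-empty clusters.
#' @return `list(widths = named numeric, avg = numeric)`.
#' @export
silhouetteWidths <- function(D, assignment) {
  d <- dissMatrix(D)
  n <- nrow(d)
  assignment <- as.integer(assignment)
  cl <- sort(unique(assignment))
  if (length(cl) < 2) stop("need at least two non-empty clusters")
  sizes <- table(factor(assignment, levels = cl))
  ind <- outer(assignment, cl, "==") * 1          # n x K membership
  sums <- d %*% ind                               # total d to each cluster
  widths <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(assignment[i], cl)
    if (sizes[ci] == 1) { widths[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1)
    b <- min(sums[i, -ci] / sizes[-ci])
    widths[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  names(widths) <- rownames(d)
  list(widths = widths, avg = mean(widths))
}

#' Select the number of clusters by average silhouette width
#'
#' Runs [pamClustering()] for each k in `kmin..kmax` and returns the k
#' maximizing the average silhouette width (ties go to the smallest k).
#'
#' @param D a [DissimilarityMatrix-class].
#' @param kmin,kmax cluster-number range (defaults 2..20); `kmax <= n - 1`.
#' @return `list(kStar, solutions, widths)` where `solutions` is a list of
#'   [ClusterSolution-class] indexed by k and `widths` the width per k.
#' @export
selectK <- function(D, kmin = 2L, kmax = 20L) {
  n <- nrow(dissMatrix(D))
  if (kmax > n - 1) stop("'kmax' must be <= n - 1")
  if (kmin < 2) stop("'kmin' must be >= 2")
  ks <- seq.int(kmin, kmax)
  solutions <- lapply(ks, function(k) pamClustering(D, k))
  names(solutions) <- as.character(ks)
  widths <- vapply(solutions, function(s) s@avgSilWidth, numeric(1))
  kStar <- ks[which.max(widths)]  # first maximum = smallest k on ties
  list(kStar = as.integer(kStar), solutions = solutions,
       widths = setNames(widths, as.character(ks)))
}

#' Savannah permutation null for cluster validity
#'
#' Computes the average silhouette width per k on the original data, then for
#' each permutation replicate independently permutes every feature column
#' (replicate seed = `seed + replicate`), recomputes the forest dissimilarity
#' and the width per k.  Real cluster structure shows as original widths far
#' above the permuted envelope; absence of structure as original widths
#' within it.
#'
#' @param pset a preprocessed [PhenotypeSet-class].
#' @param ntree trees per forest (default 2000 at permutation scale).
#' @param nPermutations number of permuted replicates (>= 1).
#' @param kmin,kmax cluster-number range.
#' @param seed master seed; the original-data forest uses it directly.
#' @param mtry,oobProx passed to [rfDissimilarity()].
#' @return a [SavannahResult-class].
#' @export
savannah <- function(pset, ntree = 2000L, nPermutations = 100L,
                     kmin = 2L, kmax = 20L, seed = 1L, mtry = NULL,
                     oobProx = FALSE) {
  if (nPermutations < 1) stop("'nPermutations' must be >= 1")
  ks <- seq.int(kmin, kmax)
  D0 <- rfDissimilarity(pset, ntree = ntree, mtry = mtry, seed = seed,
                        oobProx = oobProx)
  orig <- selectK(D0, kmin, kmax)$widths
  perm <- matrix(NA_real_, nPermutations, length(ks),
                 dimnames = list(NULL, as.character(ks)))
  for (r in seq_len(nPermutations)) {
    permSeed <- seed + r
    shuffled <- syntheticContrast(pset, seed = permSeed)
    Dr <- rfDissimilarity(shuffled, ntree = ntree, mtry = mtry,
                          seed = permSeed, oobProx = oobProx)
    perm[r, ] <- selectK(Dr, kmin, kmax)$widths
  }
  new("SavannahResult", kGrid = as.integer(ks), originalWidths = orig,
      permutedWidths = perm, nPermutations = as.integer(nPermutations),
      ntree = as.integer(ntree), seed = as.integer(seed))
}

#' Long-format table of a Savannah run
#'
#' Plot-ready long format: one row per (replicate, k); replicate 0 is the
#' original data.
#'
#' @param x a [SavannahResult-class].
#' @return data.frame with columns `replicate`, `k`, `width`.
#' @export
savannahTable <- function(x) {
  orig <- data.frame(replicate = 0L, k = x@kGrid, width = x@originalWidths)
  perm <- data.frame(
    replicate = rep(seq_len(x@nPermutations), each = length(x@kGrid)),
    k = rep(x@kGrid, x@nPermutations),
    width = as.vector(t(x@permutedWidths)))
  rbind(orig, perm)
}

#' Agreement between a clustering and class labels
#'
#' The maximum, over one-to-one mappings of clusters onto label classes
#' (optimal assignment on the contingency table; unmapped clusters contribute
#' nothing), of the fraction of samples whose mapped cluster equals their
#' label.  Invariant to cluster renumbering.
#'
#' @param assignment integer cluster index per sample.
#' @param labels class label per sample (no missing values).
#' @return agreement fraction in [0, 1].
#' @export
clusterLabelAgreement <- function(assignment, labels) {
  if (anyNA(labels) || is.null(labels)) stop("labels missing for some samples")
  if (length(assignment) != length(labels))
    stop("assignment and labels must align")
  tab <- table(assignment, labels)
  if (nrow(tab) > 20 || ncol(tab) > 20)
    stop("at most 20 clusters/classes supported")
  .assignmentMax(unclass(tab)) / length(labels)
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers \eqn{-\tfrac12 D^2}, takes the top `dims` eigenpairs and
#' scales eigenvectors by the square root of their eigenvalues.  Dimensions
#' with negative eigenvalues are dropped (their count is reported in the
#' `"nDropped"` attribute); zero eigenvalues yield zero coordinates.  The
#' sign of each axis is fixed by making its first nonzero coordinate
#' positive.
#'
#' @param D a [DissimilarityMatrix-class].
#' @param dims requested embedding dimension (default 2); at most n.
#' @return n-by-`<= dims`, numeric coordinate matrix with attribute
#'   `nDropped`.
#' @export
classicalMDS <- function(D, dims = 2L) {
  d <- dissMatrix(D)
  n <- nrow(d)
  if (dims > n) stop("'dims' must be <= n")
  B <- -0.5 * d^2
  B <- sweep(B, 1, rowMeans(B))
  B <- sweep(B, 2, colMeans(B))  # two sweeps = full double centering
  # numerically symmetrize before eigendecomposition
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  take <- seq_len(min(dims, n))
  ev <- eg$values[take]
  tol <- 1e-9 * max(1, abs(eg$values[1]))
  keep <- ev > -tol
  nDropped <- sum(!keep)
  ev <- pmax(ev[keep], 0)
  coords <- eg$vectors[, take, drop = FALSE][, keep, drop = FALSE]
  coords <- sweep(coords, 2, sqrt(ev), `*`)
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("MDS", seq_len(ncol(coords)))
  attr(coords, "nDropped") <- nDropped
  coords
}
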