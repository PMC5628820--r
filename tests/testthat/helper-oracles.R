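# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive (loops, exhaustive enumeration) and share no code with
# the implementation they check.

smallSpec <- function(seed = 3, signal = 0.9, coupling = 0.5) {
  cohortSpec(nPerClass = c(20, 15, 18),
             nNonExtreme = c(VP = 8, PK = 7, VK = 7),
             nFeatures = 30, nInformative = 18,
             levelsPerFeature = c(3, 2, 4), signalStrength = signal,
             nBlocks = 5, blockCoupling = coupling, missingRate = 0.03,
             seed = seed)
}

randomDissimilarity <- function(n, seed = 1) {
  set.seed(seed)
  d <- matrix(runif(n * n), n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  DissimilarityMatrix(d)
}

# silhouette widths straight from the definition, one sample at a time
bruteSilhouette <- function(d, cl) {
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- Inf
    for (g in setdiff(unique(cl), cl[i]))
      b <- min(b, mean(d[i, cl == g]))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# optimal k-medoid cost by exhaustive search over all medoid sets
brutePamCost <- function(d, k) {
  n <- nrow(d)
  best <- Inf
  for (med in asplit(utils::combn(n, k), 2)) {
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    best <- min(best, cost)
  }
  best
}

# AUC by looping over every (positive, negative) pair
bruteAuc <- function(score, truth) {
  pos <- score[truth]
  neg <- score[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# agreement by exhaustive search over all one-to-one cluster->class maps
bruteAgreement <- function(assignment, labels) {
  tab <- unclass(table(assignment, labels))
  n <- max(nrow(tab), ncol(tab))
  A <- matrix(0, n, n)
  A[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- 0
  for (p in perms(seq_len(n)))
    best <- max(best, sum(A[cbind(seq_len(n), p)]))
  best / sum(tab)
}

cramersV <- function(x, y) {
  tab <- table(x, y)
  if (min(dim(tab)) < 2) return(0)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
  unname(sqrt(chi / (sum(tab) * (min(dim(tab)) - 1))))
}

# mean pairwise Cramer's V among feature columns of a character matrix
meanPairwiseV <- function(m) {
  p <- ncol(m)
  vs <- c()
  for (i in seq_len(p - 1)) for (j in seq.int(i + 1, p))
    vs <- c(vs, cramersV(m[, i], m[, j]))
  mean(vs)
}

informativeIds <- function(spec) sprintf("Q%03d", seq_len(spec@nInformative))
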