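# PAM, silhouette selection, the permutation null, cluster-label agreement
# and classical MDS, each checked against an independent oracle where one
# exists.

test_that("PAM handles the degenerate cluster numbers and finds optimal pairs", {
  D <- randomDissimilarity(8, seed = 2)
  d <- dissMatrix(D)
  # k = n: every sample its own medoid at zero cost
  solN <- pamClustering(D, 8)
  expect_equal(solN@cost, 0)
  expect_identical(solN@medoids, rownames(d))
  # k = 1: the sample minimizing total dissimilarity
  sol1 <- pamClustering(D, 1)
  expect_identical(sol1@medoids, rownames(d)[which.min(colSums(d))])
  expect_equal(sol1@cost, min(colSums(d)))
  # k = 2 on small instances matches exhaustive medoid search
  for (seed in 1:10) {
    Di <- randomDissimilarity(8, seed = seed)
    expect_equal(pamClustering(Di, 2)@cost, brutePamCost(dissMatrix(Di), 2))
  }
  expect_error(pamClustering(D, 9), "k")
  expect_error(pamClustering(D, 0), "k")
})

test_that("PAM assigns every sample to its nearest medoid", {
  for (seed in 1:5) {
    D <- randomDissimilarity(25, seed = seed)
    sol <- pamClustering(D, 4)
    d <- dissMatrix(D)
    mi <- match(sol@medoids, rownames(d))
    for (i in seq_len(25))
      expect_equal(d[i, mi[sol@assignment[i]]], min(d[i, mi]))
  }
})

test_that("silhouette widths match the brute-force definition and conventions", {
  # perfect two-cluster geometry: all widths 1
  d <- matrix(0.8, 6, 6)
  d[1:3, 1:3] <- 0; d[4:6, 4:6] <- 0; diag(d) <- 0
  dimnames(d) <- list(letters[1:6], letters[1:6])
  s <- silhouetteWidths(DissimilarityMatrix(d), c(1, 1, 1, 2, 2, 2))
  expect_equal(unname(s$widths), rep(1, 6))
  expect_equal(s$avg, 1)
  # singleton convention: s = 0
  s2 <- silhouetteWidths(DissimilarityMatrix(d), c(1, 1, 1, 2, 2, 3))
  expect_equal(unname(s2$widths[6]), 0)
  # random instances against the naive oracle
  for (seed in 1:5) {
    D <- randomDissimilarity(30, seed = seed)
    set.seed(seed)
    cl <- sample(1:3, 30, replace = TRUE)
    s3 <- silhouetteWidths(D, cl)
    expect_lt(max(abs(unname(s3$widths) - bruteSilhouette(dissMatrix(D), cl))),
              1e-12)
    # cross-check against the cluster package's implementation
    ref <- cluster::silhouette(cl, stats::as.dist(dissMatrix(D)))
    expect_lt(max(abs(unname(s3$widths) - ref[, "sil_width"])), 1e-12)
  }
  expect_error(silhouetteWidths(randomDissimilarity(5), rep(1, 5)),
               "two non-empty clusters")
})

test_that("selectK maximizes the average width, ties to the smallest k", {
  # two ideal blocks: k = 2 wins with width 1
  d <- matrix(1, 12, 12)
  d[1:6, 1:6] <- 0; d[7:12, 7:12] <- 0; diag(d) <- 0
  dimnames(d) <- list(sprintf("s%02d", 1:12), sprintf("s%02d", 1:12))
  sel <- selectK(DissimilarityMatrix(d), 2, 6)
  expect_equal(sel$kStar, 2L)
  expect_equal(unname(sel$widths["2"]), 1)
  # fully tied widths (all-equal dissimilarities): smallest k returned
  dt <- matrix(0.5, 10, 10); diag(dt) <- 0
  dimnames(dt) <- list(sprintf("t%02d", 1:10), sprintf("t%02d", 1:10))
  selT <- selectK(DissimilarityMatrix(dt), 2, 5)
  expect_equal(selT$kStar, 2L)
  expect_error(selectK(DissimilarityMatrix(dt), 2, 10), "kmax")
})

test_that("cluster-label agreement equals the exhaustive mapping optimum", {
  # relabeling invariance: permuted cluster ids still give agreement 1
  labels <- rep(c("V", "P", "K"), times = c(6, 5, 4))
  assignment <- c(3, 2, 1)[match(labels, c("V", "P", "K"))]
  expect_equal(clusterLabelAgreement(assignment, labels), 1)
  # one flipped sample in a balanced 2x2 design: 19/20
  lab2 <- rep(c("A", "B"), each = 10)
  asg2 <- c(rep(1, 10), rep(2, 10)); asg2[1] <- 2
  expect_equal(clusterLabelAgreement(asg2, lab2), 19 / 20)
  # random contingencies, square and rectangular, against brute force
  for (seed in 1:10) {
    set.seed(seed)
    nC <- sample(2:4, 1); nL <- sample(2:4, 1)
    asg <- sample(seq_len(nC), 40, replace = TRUE)
    lab <- sample(LETTERS[seq_len(nL)], 40, replace = TRUE)
    expect_equal(clusterLabelAgreement(asg, lab), bruteAgreement(asg, lab))
  }
  expect_error(clusterLabelAgreement(c(1, 2), c("A", NA)), "missing")
})

test_that("classical MDS reproduces Euclidean-realizable geometries", {
  # all-zero dissimilarities embed at the origin
  d0 <- matrix(0, 5, 5)
  dimnames(d0) <- list(letters[1:5], letters[1:5])
  c0 <- classicalMDS(DissimilarityMatrix(d0), 2)
  expect_equal(max(abs(c0)), 0)
  # collinear points with gaps 1, 2, 3: pairwise distances recovered
  x <- c(0, 1, 3, 6)
  d <- abs(outer(x, x, "-")) / 6   # scale into [0,1]
  dimnames(d) <- list(paste0("p", 1:4), paste0("p", 1:4))
  cc <- classicalMDS(DissimilarityMatrix(d), 2)
  emb <- as.matrix(dist(cc))
  expect_lt(max(abs(emb - d)), 1e-9)
  # embedded distances invariant to sample reordering
  ord <- c(3, 1, 4, 2)
  cc2 <- classicalMDS(DissimilarityMatrix(d[ord, ord]), 2)
  emb2 <- as.matrix(dist(cc2))[order(ord), order(ord)]
  expect_lt(max(abs(emb2 - emb)), 1e-9)
  expect_error(classicalMDS(DissimilarityMatrix(d), 5), "dims")
})

test_that("the permutation null flattens silhouette structure on a real cohort", {
  spec <- smallSpec(seed = 13)
  ext <- generateExtreme(spec)
  sv <- savannah(ext, ntree = 800, nPermutations = 4, kmin = 2, kmax = 8,
                 seed = 3)
  expect_true(validObject(sv))
  expect_equal(dim(sv@permutedWidths), c(4L, 7L))
  # the structured data's optimum stands above every permuted width
  expect_gt(max(sv@originalWidths), max(sv@permutedWidths))
  tab <- savannahTable(sv)
  expect_equal(nrow(tab), 7 * 5)
  expect_equal(sum(tab$replicate == 0), 7)
  expect_error(savannah(ext, nPermutations = 0), "nPermutations")
})

test_that("mixture groups embed between their parent classes, away from the third", {
  spec <- smallSpec(seed = 21)
  model <- cohortModel(spec)
  ext <- generateExtreme(spec, model)
  ne <- generateNonExtreme(spec, model)
  all <- PhenotypeSet(rbind(traitMatrix(ext), traitMatrix(ne)),
                      labels = c(phenoLabels(ext), phenoLabels(ne)))
  D <- rfDissimilarity(all, ntree = 2000, seed = 2)
  coords <- classicalMDS(D, 2)
  lab <- phenoLabels(all)
  centroid <- function(g) colMeans(coords[lab == g, , drop = FALSE])
  for (pair in list(c("VP", "V", "P", "K"), c("PK", "P", "K", "V"),
                    c("VK", "V", "K", "P"))) {
    cm <- centroid(pair[1])
    dPar <- max(sqrt(sum((cm - centroid(pair[2]))^2)),
                sqrt(sum((cm - centroid(pair[3]))^2)))
    dThird <- sqrt(sum((cm - centroid(pair[4]))^2))
    expect_lt(dPar, dThird)
  }
})
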