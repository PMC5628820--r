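# Dummy coding, the stratified split, the three classifiers with their
# feature-selection protocols, evaluation identities, and cross-cohort
# harmonization.

trainCohort <- function(seed = 3) generateExtreme(smallSpec(seed = seed))

test_that("dummy coding uses modal reference levels and partitions by feature", {
  ps <- PhenotypeSet(
    data.frame(f3 = c("a", "b", "c", "a", "a", "b"),
               f2 = c("x", "y", "x", "y", "x", "y"),
               row.names = sprintf("s%d", 1:6)))
  enc <- encodeDesign(ps)
  # 3-level feature -> 2 columns; reference is the mode "a"
  expect_setequal(colnames(enc@X)[enc@parent == "f3"], c("f3=b", "f3=c"))
  # tie in f2 {x,y}: lexicographic reference "x"
  expect_identical(colnames(enc@X)[enc@parent == "f2"], "f2=y")
  # per feature, each row sets at most one indicator
  for (f in c("f3", "f2")) {
    rs <- rowSums(enc@X[, enc@parent == f, drop = FALSE])
    expect_true(all(rs %in% c(0, 1)))
  }
  expect_setequal(unique(unname(enc@parent)), c("f3", "f2"))
  # new data: unseen level scores as reference, absent feature errors by name
  new1 <- PhenotypeSet(data.frame(f3 = "z", f2 = "y", row.names = "n1"))
  Xn <- encodeWithScheme(enc@encoding, new1)@X
  expect_equal(sum(Xn[, enc@parent == "f3"]), 0)
  missingFeature <- PhenotypeSet(data.frame(f3 = "a", row.names = "n1"))
  expect_error(encodeWithScheme(enc@encoding, missingFeature), "f2")
  const <- PhenotypeSet(data.frame(f1 = c("a", "a"), row.names = c("r1", "r2")))
  expect_error(encodeDesign(const), "constant")
})

test_that("the stratified split reproduces the canonical 7/4/5 hold-out", {
  ext <- generateExtreme(cohortSpec(seed = 1))
  s <- splitTrainTest(ext, 0.9, seed = 1)
  tb <- table(phenoLabels(s$test))
  expect_equal(as.vector(tb[c("V", "P", "K")]), c(7L, 4L, 5L))
  expect_equal(length(sampleIds(s$test)), 16L)
  # union is the input, intersection empty
  expect_setequal(c(sampleIds(s$train), sampleIds(s$test)), sampleIds(ext))
  expect_length(intersect(sampleIds(s$train), sampleIds(s$test)), 0)
  # fraction 1: empty test set
  sAll <- splitTrainTest(ext, 1, seed = 1)
  expect_length(sampleIds(sAll$test), 0)
  tiny <- PhenotypeSet(traitMatrix(ext)[1:3, ],
                       labels = c("V", "V", "P"))
  expect_error(splitTrainTest(tiny, 0.9), "at least 2")
})

test_that("the lasso path starts empty and the tuned fit separates a strong cohort", {
  ext <- trainCohort()
  s <- splitTrainTest(ext, 0.9, seed = 2)
  fit <- fitLasso(s$train, seed = 2)
  # at lambda_max every coefficient is zero by construction
  cf <- coef(fit@fit, s = max(fit@fit$lambda))
  expect_true(all(vapply(cf, function(b) all(b[-1, 1] == 0), logical(1))))
  # sparsity shrinks with lambda along the path (glmnet paths allow rare
  # local re-entries; the trend must be strongly monotone)
  nz <- fit@fit$df
  expect_lt(cor(fit@fit$lambda, nz, method = "spearman"), -0.9)
  expect_equal(nz[1], 0L)
  # hold-out perfection on strong signal, and selections are signal-bearing
  expect_equal(evaluateModel(fit, s$test)@accuracy, 1)
  inf <- informativeIds(smallSpec())
  expect_lte(mean(!selectedFeatures(fit) %in% inf), 0.1)
})

test_that("elastic-net tuning scans the 11-point alpha grid and nests the lasso", {
  ext <- trainCohort(seed = 5)
  s <- splitTrainTest(ext, 0.9, seed = 2)
  enet <- fitEnet(s$train, seed = 2)
  lasso <- fitLasso(s$train, seed = 2)
  alphas <- sort(unique(enet@cvPath$alpha))
  expect_equal(alphas, c(0.01, seq(0.1, 1, by = 0.1)))
  # at alpha = 1 the elastic-net CV records coincide with the lasso's
  # (same folds, same path): the penalty identity
  pe <- enet@cvPath[enet@cvPath$alpha == 1, c("lambda", "error")]
  pl <- lasso@cvPath[, c("lambda", "error")]
  expect_equal(pe$lambda, pl$lambda)
  expect_equal(pe$error, pl$error)
  # generalization measured on a large fresh draw from the same model
  # (the in-split hold-out has only 6 samples and a grainy accuracy)
  fresh <- deriveSecondCohort(smallSpec(seed = 5), sharedFeatures = 30,
                              nPerClass = c(50, 50, 50))
  expect_gte(evaluateModel(enet, fresh)@accuracy, 0.8)
})

test_that("the mixed penalty keeps groups of correlated predictors together", {
  # a duplicated informative feature: at alpha = 0.5 both copies survive
  ext <- trainCohort(seed = 8)
  m <- traitMatrix(ext)
  m <- cbind(m, Q901 = m[, "Q001"])
  ps <- PhenotypeSet(m, labels = phenoLabels(ext))
  enc <- PrakritiML::encodeDesign(ps)
  y <- factor(phenoLabels(ps))
  cv <- glmnet::cv.glmnet(enc@X, y, family = "multinomial", alpha = 0.5,
                          type.measure = "class", nfolds = 5)
  cf <- coef(cv$glmnet.fit, s = cv$lambda.min)
  nzCols <- unique(unlist(lapply(cf, function(b)
    rownames(b)[which(b[, 1] != 0)])))
  parents <- unique(unname(enc@parent[setdiff(nzCols, "(Intercept)")]))
  expect_true(all(c("Q001", "Q901") %in% parents))
})

test_that("shadow selection confirms planted signal and rejects noise", {
  ext <- trainCohort(seed = 4)
  sel <- borutaSelect(ext, ntree = 300, maxRuns = 60, seed = 4)
  inf <- informativeIds(smallSpec())
  noise <- setdiff(featureIds(ext), inf)
  expect_gte(mean(inf %in% sel@confirmed), 0.8)
  expect_gte(mean(noise %in% sel@rejected), 0.8)
  expect_setequal(c(sel@confirmed, sel@rejected), featureIds(ext))
  expect_error(borutaSelect(ext, maxRuns = 6), "maxRuns")
})

test_that("shadow selection confirms almost nothing when labels are permuted", {
  # correlated block-mates can drag each other over the shadow maximum even
  # under a label permutation, so a handful of false confirmations is
  # irreducible; the null property is that they stay rare
  ext <- trainCohort(seed = 4)
  m <- traitMatrix(ext)
  confirmed <- integer(0)
  for (rep in 1:3) {
    set.seed(100 + rep)
    null <- PhenotypeSet(m, labels = sample(phenoLabels(ext)))
    sel <- borutaSelect(null, ntree = 300, maxRuns = 40, seed = rep)
    confirmed <- c(confirmed, length(sel@confirmed))
  }
  expect_lte(max(confirmed), 0.1 * ncol(m))
})

test_that("forest tuning follows the least-median / least-SD rule reproducibly", {
  ext <- trainCohort(seed = 3)
  inf <- informativeIds(smallSpec())
  fm1 <- tuneForest(ext, features = inf, seed = 7,
                    ntreeGrid = c(100, 300, 500), nRepeats = 2)
  fm2 <- tuneForest(ext, features = inf, seed = 7,
                    ntreeGrid = c(100, 300, 500), nRepeats = 2)
  expect_identical(c(fm1@ntree, fm1@mtry), c(fm2@ntree, fm2@mtry))
  expect_identical(fm1@tuning, fm2@tuning)
  # grid bookkeeping: every candidate scored once per stage
  expect_equal(sum(fm1@tuning$stage == "ntree"), 3)
  expect_equal(sum(fm1@tuning$stage == "mtry"),
               min(15, ceiling(sqrt(length(inf))) + 10, length(inf)))
  # strong signal: tuned forest is accurate out of bag
  expect_lte(fm1@oobError, 0.05)
  expect_error(tuneForest(ext, features = character(0)), "nonempty")
  expect_error(tuneForest(ext, features = "nope"), "nope")
})

test_that("probabilities are proper and evaluation identities hold", {
  ext <- trainCohort(seed = 6)
  s <- splitTrainTest(ext, 0.9, seed = 3)
  lasso <- fitLasso(s$train, seed = 3)
  fm <- tuneForest(s$train, features = informativeIds(smallSpec()),
                   seed = 3, ntreeGrid = c(200, 400), nRepeats = 2)
  for (model in list(lasso, fm)) {
    pr <- predictProba(model, s$test)
    expect_true(all(pr >= 0))
    expect_lt(max(abs(rowSums(pr) - 1)), 1e-9)
    expect_identical(colnames(pr), sort(c("K", "P", "V")))
    rep <- evaluateModel(model, s$test)
    n <- sum(rep@confusion)
    expect_equal(rep@accuracy, sum(diag(rep@confusion)) / n)
    expect_equal(unname(rowSums(rep@confusion)),
                 as.vector(table(factor(phenoLabels(s$test),
                                        levels = rownames(rep@confusion)))))
    tp <- diag(rep@confusion)
    expect_equal(unname(rep@sensitivity), unname(tp / rowSums(rep@confusion)))
    fp <- colSums(rep@confusion) - tp
    tn <- n - rowSums(rep@confusion) - fp
    expect_equal(unname(rep@specificity), unname(tn / (tn + fp)))
  }
  expect_error(evaluateModel(lasso, splitTrainTest(ext, 1, 1)$test), "empty")
})

test_that("feature harmonization and cross-cohort validation behave symmetrically", {
  spec <- smallSpec(seed = 14)
  a <- generateExtreme(spec)
  b <- deriveSecondCohort(spec, sharedFeatures = 22,
                          nPerClass = c(15, 15, 15))
  h <- harmonizeFeatures(a, b)
  expect_identical(h$shared, featureIds(a)[1:22])
  expect_identical(featureIds(h$a), featureIds(h$b))
  # identical feature sets: identity
  h2 <- harmonizeFeatures(a, a)
  expect_identical(traitMatrix(h2$a), traitMatrix(a))
  disjoint <- PhenotypeSet(matrix("a", 3, 2,
                                  dimnames = list(paste0("s", 1:3),
                                                  c("z1", "z2"))))
  expect_error(harmonizeFeatures(a, disjoint), "shared")
  # validating a cohort against itself equals in-cohort evaluation
  xv <- crossCohortValidate(a, a, method = "lasso", seed = 5)
  direct <- evaluateModel(xv$model, a)
  expect_identical(xv$report@confusion, direct@confusion)
  expect_gte(min(xv$report@sensitivity), 0.8)
})
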