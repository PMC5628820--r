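# The cohort generator: study-shaped defaults, determinism, and the latent
# class-conditional structure every downstream stage relies on.

test_that("default cohorts reproduce the study shape deterministically", {
  spec <- cohortSpec(seed = 1)
  ext <- generateExtreme(spec)
  expect_equal(dim(traitMatrix(ext)), c(147L, 133L))
  expect_equal(as.vector(table(phenoLabels(ext))[c("V", "P", "K")]),
               c(66L, 35L, 46L))
  ne <- generateNonExtreme(spec)
  expect_equal(length(sampleIds(ne)), 106L)
  expect_equal(as.vector(table(phenoLabels(ne))[c("VP", "PK", "VK")]),
               c(40L, 33L, 33L))
  b <- deriveSecondCohort(spec)
  expect_equal(dim(traitMatrix(b)), c(96L, 106L))
  expect_identical(featureIds(b), featureIds(ext)[1:106])

  # identical spec + seed => byte-identical serialized cohorts
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  writePhenotypeTSV(generateExtreme(spec), f1)
  writePhenotypeTSV(generateExtreme(cohortSpec(seed = 1)), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("informative features concentrate the stated mass on each class's preferred level", {
  spec <- cohortSpec(nPerClass = c(1000, 1000, 1000),
                     nNonExtreme = c(VP = 10), nFeatures = 20,
                     nInformative = 12, signalStrength = 0.9, nBlocks = 4,
                     blockCoupling = 0.5, seed = 11)
  model <- cohortModel(spec)
  ext <- generateExtreme(spec, model)
  m <- traitMatrix(ext)
  labels <- phenoLabels(ext)
  levLab <- c("a", "b", "c", "d")
  for (j in seq_len(spec@nInformative)) {
    for (ci in seq_along(spec@classNames)) {
      pref <- levLab[model$pref[ci, j]]
      freq <- mean(m[labels == spec@classNames[ci], j] == pref)
      expect_lt(abs(freq - 0.9), 0.03)
    }
  }
})

test_that("zero signal makes every feature's distribution independent of class", {
  spec <- cohortSpec(nPerClass = c(1000, 1000, 1000),
                     nNonExtreme = c(VP = 10), nFeatures = 30,
                     nInformative = 30, signalStrength = 0, nBlocks = 5,
                     seed = 7)
  ext <- generateExtreme(spec)
  m <- traitMatrix(ext)
  labels <- phenoLabels(ext)
  pvals <- apply(m, 2, function(col)
    suppressWarnings(chisq.test(table(col, labels))$p.value))
  # p-values should look uniform: no excess of small ones, central mean
  expect_lt(mean(pvals < 0.05), 0.15)
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
})

test_that("mixture samples are feature-wise midpoints of their parents", {
  spec <- cohortSpec(nPerClass = c(1500, 1500, 10),
                     nNonExtreme = c(VP = 1000, VV = 200),
                     nFeatures = 20, nInformative = 12,
                     signalStrength = 0.85, nBlocks = 4, seed = 19)
  model <- cohortModel(spec)
  ext <- generateExtreme(spec, model)
  ne <- generateNonExtreme(spec, model)
  mE <- traitMatrix(ext); mN <- traitMatrix(ne)
  labE <- phenoLabels(ext); labN <- phenoLabels(ne)
  levLab <- c("a", "b", "c", "d")
  diffs <- vapply(seq_len(spec@nInformative), function(j) {
    prefV <- levLab[model$pref[1, j]]
    fV <- mean(mE[labE == "V", j] == prefV)
    fP <- mean(mE[labE == "P", j] == prefV)
    fMix <- mean(mN[labN == "VP", j] == prefV)
    fMix - (fV + fP) / 2
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
  # degenerate pair (V,V) reproduces the pure class-V marginals
  dVV <- vapply(seq_len(spec@nInformative), function(j) {
    prefV <- levLab[model$pref[1, j]]
    mean(mN[labN == "VV", j] == prefV) - mean(mE[labE == "V", j] == prefV)
  }, numeric(1))
  expect_lt(max(abs(dVV)), 0.1)
})

test_that("block coupling controls within-block concordance", {
  # full coupling + shared preferred levels => identical columns per sample
  spec1 <- cohortSpec(nPerClass = c(60, 50, 40), nNonExtreme = c(VP = 5),
                      nFeatures = 12, nInformative = 12,
                      levelsPerFeature = 3, signalStrength = 0.85,
                      nBlocks = 2, blockCoupling = 1, seed = 5)
  m1 <- traitMatrix(generateExtreme(spec1))
  # features 1 and 4 sit in the same block and share preferred levels
  # (preferences cycle with period 3)
  expect_identical(m1[, 1], m1[, 4])
  expect_identical(m1[, 2], m1[, 5])

  # no coupling => within-block association indistinguishable from noise
  spec0 <- cohortSpec(nPerClass = c(500, 300, 200), nNonExtreme = c(VP = 5),
                      nFeatures = 12, nInformative = 12,
                      levelsPerFeature = 3, signalStrength = 0.85,
                      nBlocks = 2, blockCoupling = 0, seed = 5)
  ext0 <- generateExtreme(spec0)
  m0 <- traitMatrix(ext0)[phenoLabels(ext0) == "V", 1:6]
  expect_lt(meanPairwiseV(m0), 0.1)
})

test_that("missingness injection is MCAR at the requested rate and reproducible", {
  spec <- cohortSpec(seed = 2)
  ext <- generateExtreme(spec)
  expect_identical(injectMissing(ext, 0), ext)
  miss <- injectMissing(ext, 0.04, seed = 9)
  expect_lt(abs(mean(is.na(traitMatrix(miss))) - 0.04), 0.01)
  expect_identical(phenoLabels(miss), phenoLabels(ext))
  expect_identical(traitMatrix(injectMissing(ext, 0.04, seed = 9)),
                   traitMatrix(miss))
  expect_error(injectMissing(ext, 1), "rate")
  expect_error(injectMissing(ext, -0.1), "rate")
})

test_that("invalid generator inputs fail with the offending field named", {
  expect_error(cohortSpec(nFeatures = 10, nInformative = 11), "nInformative")
  expect_error(cohortSpec(signalStrength = 1.2), "signalStrength")
  expect_error(cohortSpec(missingRate = 0.5), "missingRate")
  expect_error(cohortSpec(levelsPerFeature = 5), "levelsPerFeature")
  expect_error(cohortSpec(blockCoupling = -0.1), "blockCoupling")
  spec <- cohortSpec(nNonExtreme = c(VX = 10))
  expect_error(generateNonExtreme(spec), "unknown parent class")
  expect_error(deriveSecondCohort(cohortSpec(), sharedFeatures = 200),
               "sharedFeatures")
})

test_that("a second cohort drawn from the same model matches cohort A's distributions", {
  spec <- cohortSpec(nPerClass = c(1000, 1000, 1000),
                     nNonExtreme = c(VP = 10), nFeatures = 20,
                     nInformative = 12, signalStrength = 0.85, nBlocks = 4,
                     seed = 23)
  model <- cohortModel(spec)
  a <- generateExtreme(spec, model)
  b <- deriveSecondCohort(spec, sharedFeatures = 20,
                          nPerClass = c(1000, 1000, 1000), seed = 99)
  mA <- traitMatrix(a); mB <- traitMatrix(b)
  labA <- phenoLabels(a); labB <- phenoLabels(b)
  levLab <- c("a", "b", "c", "d")
  for (j in seq_len(spec@nInformative)) {
    for (ci in seq_along(spec@classNames)) {
      pref <- levLab[model$pref[ci, j]]
      cl <- spec@classNames[ci]
      dif <- mean(mA[labA == cl, j] == pref) - mean(mB[labB == cl, j] == pref)
      expect_lt(abs(dif), 0.05)
    }
  }
  expect_identical(featureIds(deriveSecondCohort(spec, sharedFeatures = 20)),
                   featureIds(a))
})
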