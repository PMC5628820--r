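# Synthetic questionnaire cohorts with latent constitution-type structure.
# The generator is fully determined by a CohortSpec: the same spec + seed
# always reproduces the same cohort byte-for-byte.

.LEVEL_LABELS <- c("a", "b", "c", "d")

#' Construct a CohortSpec
#'
#' Defaults mirror the cohort shape the package's analyses are calibrated on:
#' three extreme classes of 66/35/46 samples, 106 non-extreme mixtures split
#' 40/33/33 across the VP/PK/VK pairs, 133 features of which the first 80 are
#' class-informative, 12 contiguous correlated blocks, signal strength 0.85,
#' block coupling 0.5 and 3% MCAR missingness.
#'
#' @param classNames extreme class names.
#' @param nPerClass extreme sample count per class.
#' @param nNonExtreme named mixture counts; names are class pairs, either two
#'   single-letter class names concatenated (`"VP"`) or joined by `+`.
#' @param nFeatures,nInformative total and informative feature counts.
#' @param levelsPerFeature level count (2..4) per feature; recycled.
#' @param signalStrength,nBlocks,blockCoupling,missingRate,seed see
#'   [CohortSpec-class].
#' @return a validated [CohortSpec-class].
#' @examples
#' spec <- cohortSpec(seed = 1)
#' generateExtreme(spec)
#' @export
cohortSpec <- function(classNames = c("V", "P", "K"),
                       nPerClass = c(66, 35, 46),
                       nNonExtreme = c(VP = 40, PK = 33, VK = 33),
                       nFeatures = 133, nInformative = 80,
                       levelsPerFeature = c(3, 2, 4),
                       signalStrength = 0.85, nBlocks = 12,
                       blockCoupling = 0.5, missingRate = 0.03, seed = 1) {
  new("CohortSpec", classNames = as.character(classNames),
      nPerClass = as.integer(nPerClass),
      nNonExtreme = setNames(as.integer(nNonExtreme), names(nNonExtreme)),
      nFeatures = as.integer(nFeatures),
      nInformative = as.integer(nInformative),
      levelsPerFeature = as.integer(rep(levelsPerFeature,
                                        length.out = nFeatures)),
      signalStrength = signalStrength, nBlocks = as.integer(nBlocks),
      blockCoupling = blockCoupling, missingRate = missingRate,
      seed = as.integer(seed))
}

#' Latent generative model implied by a CohortSpec
#'
#' Deterministically derives, from the spec and its seed, everything the
#' sampling steps share: feature ids, the contiguous block partition, each
#' class's preferred level per informative feature (levels cycle with the
#' class index, so 2-level features cannot separate three classes), and the
#' single multinomial shared by all non-informative features.
#'
#' @param spec a [CohortSpec-class].
#' @return an opaque list consumed by [generateExtreme()],
#'   [generateNonExtreme()] and [deriveSecondCohort()].
#' @export
cohortModel <- function(spec) {
  validObject(spec)
  p <- spec@nFeatures
  L <- spec@levelsPerFeature
  K <- length(spec@classNames)
  informative <- seq_len(p) <= spec@nInformative
  block <- as.integer(cut(seq_len(p), spec@nBlocks, labels = FALSE))
  # preferred level of class c for informative feature j cycles with c and j
  pref <- matrix(NA_integer_, K, p)
  for (j in which(informative))
    pref[, j] <- ((j + seq_len(K) - 2L) %% L[j]) + 1L
  set.seed(spec@seed)
  noiseProbs <- vector("list", p)
  for (j in which(!informative)) {
    g <- rgamma(L[j], shape = 5, rate = 1)
    noiseProbs[[j]] <- g / sum(g)
  }
  list(spec = spec, featureIds = sprintf("Q%03d", seq_len(p)),
       informative = informative, block = block, pref = pref,
       noiseProbs = noiseProbs)
}

# class-conditional level distribution of feature j for class index ci,
# returned as (level order, cumulative probabilities) for inverse-CDF draws.
# Mass signalStrength sits on the preferred level, the remainder is uniform
# on the others; at or below the uniform baseline 1/L no preference is
# expressible and the distribution is uniform over all levels.
.condDist <- function(model, j, ci) {
  L <- model$spec@levelsPerFeature[j]
  if (!model$informative[j]) {
    return(list(ord = seq_len(L), cum = cumsum(model$noiseProbs[[j]])))
  }
  s <- model$spec@signalStrength
  if (s <= 1 / L) return(list(ord = seq_len(L), cum = seq_len(L) / L))
  pf <- model$pref[ci, j]
  ord <- c(pf, setdiff(seq_len(L), pf))
  list(ord = ord, cum = cumsum(c(s, rep((1 - s) / (L - 1), L - 1))))
}

.mapLevels <- function(u, dist) {
  idx <- pmin(findInterval(u, dist$cum) + 1L, length(dist$ord))
  .LEVEL_LABELS[dist$ord[idx]]
}

# draw n samples of a single extreme class (index ci), with block coupling
.drawClass <- function(model, ci, n) {
  spec <- model$spec
  p <- spec@nFeatures
  vals <- matrix(NA_character_, n, p)
  Ublock <- matrix(runif(n * spec@nBlocks), n, spec@nBlocks)
  for (j in seq_len(p)) {
    u <- runif(n)
    # coupling copies the block's latent preference draw; below the uniform
    # baseline (s <= 1/L) a feature has no preference to copy and samples
    # independently, so a zero-signal cohort is exchangeable with its
    # column permutations
    couples <- model$informative[j] && spec@blockCoupling > 0 &&
      spec@signalStrength > 1 / spec@levelsPerFeature[j]
    if (couples) {
      z <- runif(n) < spec@blockCoupling
      u[z] <- Ublock[z, model$block[j]]
    }
    vals[, j] <- .mapLevels(u, .condDist(model, j, ci))
  }
  vals
}

#' Generate the extreme-class cohort
#'
#' Samples each class from its class-conditional multinomials; informative
#' features within a block share a per-sample latent uniform with probability
#' `blockCoupling`, inducing within-block correlation.  No missing values are
#' introduced at this stage (see [injectMissing()]).
#'
#' @param spec a [CohortSpec-class].
#' @param model generator state from [cohortModel()]; rebuilt when omitted.
#' @param seed sampling seed; defaults to `spec@seed + 1`.
#' @param idPrefix prefix of the generated sample ids.
#' @return a labeled [PhenotypeSet-class] with `sum(spec@nPerClass)` samples.
#' @export
generateExtreme <- function(spec, model = cohortModel(spec),
                            seed = spec@seed + 1L, idPrefix = "S") {
  validObject(spec)
  set.seed(seed)
  parts <- vector("list", length(spec@classNames))
  for (ci in seq_along(spec@classNames))
    parts[[ci]] <- .drawClass(model, ci, spec@nPerClass[ci])
  vals <- do.call(rbind, parts)
  labels <- rep(spec@classNames, spec@nPerClass)
  rownames(vals) <- sprintf("%s%03d", idPrefix, seq_len(nrow(vals)))
  colnames(vals) <- model$featureIds
  PhenotypeSet(vals, labels = labels)
}

.parsePair <- function(pairName, classNames) {
  parts <- strsplit(pairName, "+", fixed = TRUE)[[1]]
  if (length(parts) == 1 && all(nchar(classNames) == 1))
    parts <- strsplit(pairName, "")[[1]]
  idx <- match(parts, classNames)
  if (length(idx) != 2 || anyNA(idx))
    stop("unknown parent class in mixture pair '", pairName, "'")
  idx
}

#' Generate the non-extreme (mixture) cohort
#'
#' Each mixture sample with parent pair (A, B) draws every feature from
#' parent A's class-conditional distribution with probability 1/2 and from
#' B's otherwise, independently per feature, so mixtures sit between their
#' parent classes in phenotype space.
#'
#' @param spec a [CohortSpec-class]; mixture pairs and counts come from
#'   `spec@nNonExtreme`.
#' @param model generator state from [cohortModel()] (the same preferred-level
#'   assignments as the extreme cohort).
#' @param seed sampling seed; defaults to `spec@seed + 2`.
#' @return a [PhenotypeSet-class] labeled with the pair names.
#' @export
generateNonExtreme <- function(spec, model = cohortModel(spec),
                               seed = spec@seed + 2L) {
  validObject(spec)
  if (length(spec@nNonExtreme) == 0 || sum(spec@nNonExtreme) == 0)
    stop("spec defines no non-extreme samples")
  if (is.null(names(spec@nNonExtreme)))
    stop("nNonExtreme must be named by class pairs")
  set.seed(seed)
  p <- spec@nFeatures
  parts <- list()
  for (pairName in names(spec@nNonExtreme)) {
    n <- spec@nNonExtreme[[pairName]]
    if (n == 0) next
    idx <- .parsePair(pairName, spec@classNames)
    vals <- matrix(NA_character_, n, p)
    for (j in seq_len(p)) {
      u <- runif(n)
      pickA <- runif(n) < 0.5
      levA <- .mapLevels(u, .condDist(model, j, idx[1]))
      levB <- .mapLevels(u, .condDist(model, j, idx[2]))
      vals[, j] <- ifelse(pickA, levA, levB)
    }
    parts[[pairName]] <- vals
  }
  vals <- do.call(rbind, parts)
  labels <- rep(names(spec@nNonExtreme)[spec@nNonExtreme > 0],
                spec@nNonExtreme[spec@nNonExtreme > 0])
  rownames(vals) <- sprintf("N%03d", seq_len(nrow(vals)))
  colnames(vals) <- model$featureIds
  PhenotypeSet(vals, labels = labels)
}

#' Inject missing-completely-at-random values
#'
#' Each cell is independently set to `NA` with probability `rate`; labels are
#' untouched.
#'
#' @param pset a [PhenotypeSet-class].
#' @param rate missingness probability in [0, 1).
#' @param seed RNG seed.
#' @return a [PhenotypeSet-class] with missing cells.
#' @export
injectMissing <- function(pset, rate, seed = 1L) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("'rate' must lie in [0, 1)")
  if (rate == 0) return(pset)
  m <- traitMatrix(pset)
  set.seed(seed)
  m[runif(length(m)) < rate] <- NA_character_
  PhenotypeSet(m, labels = phenoLabels(pset))
}

#' Derive a second cohort sharing part of the feature panel
#'
#' Draws a new cohort from the same class-conditional distributions as the
#' parent spec (same generator state) and restricts it to the first
#' `sharedFeatures` features — informative features first, then noise — the
#' deterministic harmonization rule for cross-cohort validation.
#'
#' @param spec the parent [CohortSpec-class].
#' @param sharedFeatures number of features shared with the parent cohort.
#' @param nPerClass per-class sample counts of the new cohort.
#' @param seed sampling seed; defaults to `spec@seed + 7`.
#' @return a labeled [PhenotypeSet-class] of `sum(nPerClass)` samples by
#'   `sharedFeatures` features.
#' @export
deriveSecondCohort <- function(spec, sharedFeatures = 106L,
                               nPerClass = c(32, 32, 32),
                               seed = spec@seed + 7L) {
  validObject(spec)
  if (sharedFeatures > spec@nFeatures)
    stop("'sharedFeatures' exceeds the spec's feature count")
  if (length(nPerClass) != length(spec@classNames))
    stop("'nPerClass' must give one count per class")
  model <- cohortModel(spec)
  set.seed(seed)
  parts <- vector("list", length(spec@classNames))
  for (ci in seq_along(spec@classNames))
    parts[[ci]] <- .drawClass(model, ci, nPerClass[ci])
  vals <- do.call(rbind, parts)
  labels <- rep(spec@classNames, nPerClass)
  rownames(vals) <- sprintf("T%03d", seq_len(nrow(vals)))
  colnames(vals) <- model$featureIds
  PhenotypeSet(vals[, seq_len(sharedFeatures), drop = FALSE], labels = labels)
}
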