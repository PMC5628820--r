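# Shadow-feature ("Boruta") relevance selection, re-implemented around
# randomForest permutation importance.  Each run appends one independently
# permuted shadow copy of every still-active feature; a real feature scores a
# "hit" when its raw permutation importance (OOB accuracy drop) exceeds the
# maximum shadow importance.  Hit counts are tested against Binomial(runs,
# 1/2): significantly high -> Confirmed (the feature stays in the model),
# significantly low -> Rejected (removed).  Whatever is still undecided at
# maxRuns is resolved by comparing its median importance to the median of
# the shadow maxima.

#' Boruta-style shadow feature selection
#'
#' @param pset a labeled, preprocessed [PhenotypeSet-class].
#' @param ntree trees per forest run (default 500).
#' @param maxRuns maximum shadow runs; must be >= 7 (a two-sided binomial
#'   test cannot reach p < 0.01 in fewer).
#' @param pThreshold binomial-test significance level (default 0.01).
#' @param seed RNG seed.
#' @return a [BorutaResult-class].
#' @export
borutaSelect <- function(pset, ntree = 500L, maxRuns = 100L,
                         pThreshold = 0.01, seed = 1L) {
  if (maxRuns < 7) stop("'maxRuns' must be >= 7")
  labels <- phenoLabels(pset)
  if (is.null(labels)) stop("labels required")
  x <- traitTable(pset)
  y <- factor(labels, levels = sort(unique(labels)))
  feats <- colnames(x)
  status <- setNames(rep("Tentative", length(feats)), feats)
  hits <- setNames(rep(0L, length(feats)), feats)
  impHist <- setNames(vector("list", length(feats)), feats)
  shadowMaxHist <- numeric(0)
  set.seed(seed)
  run <- 0L
  while (run < maxRuns && any(status == "Tentative")) {
    run <- run + 1L
    active <- feats[status != "Rejected"]
    xa <- x[, active, drop = FALSE]
    shadow <- as.data.frame(lapply(xa, sample))
    names(shadow) <- paste0(".shadow.", active)
    rf <- randomForest::randomForest(
      x = cbind(xa, shadow), y = y, ntree = as.integer(ntree),
      importance = TRUE, keep.forest = FALSE)
    imp <- rf$importance[, "MeanDecreaseAccuracy"]
    shadowMax <- max(imp[names(shadow)])
    shadowMaxHist <- c(shadowMaxHist, shadowMax)
    for (f in active) impHist[[f]] <- c(impHist[[f]], unname(imp[f]))
    tent <- feats[status == "Tentative"]
    hits[tent] <- hits[tent] + (imp[tent] > shadowMax)
    # two-sided binomial test of hits against Binomial(run, 1/2),
    # Bonferroni-adjusted across the features still being tested (the test
    # is applied after every run; without the adjustment the sequential
    # testing confirms noise features at well above the nominal level)
    p <- 2 * pmin(pbinom(hits[tent], run, 0.5),
                  pbinom(run - hits[tent], run, 0.5))
    p <- pmin(p * length(tent), 1)
    status[tent[p < pThreshold & hits[tent] > run / 2]] <- "Confirmed"
    status[tent[p < pThreshold & hits[tent] < run / 2]] <- "Rejected"
  }
  unresolved <- feats[status == "Tentative"]
  if (length(unresolved)) {
    shadowMed <- median(shadowMaxHist)
    up <- vapply(unresolved,
                 function(f) median(impHist[[f]]) >= shadowMed, logical(1))
    status[unresolved[up]] <- "Confirmed"
    status[unresolved[!up]] <- "Rejected"
  }
  new("BorutaResult",
      confirmed = feats[status == "Confirmed"],
      rejected = feats[status == "Rejected"],
      tentative = unresolved, nRuns = run, hits = hits,
      impMedian = vapply(impHist, function(v)
        if (is.null(v)) NA_real_ else median(v), numeric(1)),
      shadowMedian = median(shadowMaxHist))
}

#' @importFrom stats pbinom
NULL
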