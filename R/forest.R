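# Random-forest classifier with the two-stage grid tuning protocol:
# twenty ntree values (500..10000 by 500), each refit nRepeats times, scored
# by least median OOB misclassification with least standard deviation as the
# tiebreak (then the smaller grid value); the same protocol then tunes mtry
# at the chosen ntree.

.tuneStage <- function(x, y, grid, nRepeats, fixed, stage) {
  med <- sdv <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    errs <- numeric(nRepeats)
    for (r in seq_len(nRepeats)) {
      args <- list(x = x, y = y, keep.forest = FALSE)
      args[[stage]] <- grid[gi]
      args <- c(args, fixed)
      rf <- do.call(randomForest::randomForest, args)
      errs[r] <- rf$err.rate[args$ntree, "OOB"]
    }
    med[gi] <- median(errs)
    sdv[gi] <- sd(errs)
  }
  best <- order(med, sdv, grid)[1]
  list(value = grid[best],
       table = data.frame(stage = stage, value = grid,
                          medianOOB = med, sdOOB = sdv))
}

#' Tune and fit a random-forest classifier on a fixed feature set
#'
#' @param pset a labeled [PhenotypeSet-class].
#' @param features feature ids to grow the forest on (normally the
#'   Boruta-confirmed set); must be nonempty.
#' @param seed RNG seed (one stream drives the whole tuning).
#' @param ntreeGrid candidate tree counts (default 500..10000 by 500).
#' @param nRepeats forests per grid point (default 5).
#' @return a [ForestModel-class].
#' @export
tuneForest <- function(pset, features = featureIds(pset), seed = 1L,
                       ntreeGrid = seq(500L, 10000L, by = 500L),
                       nRepeats = 5L) {
  if (length(features) == 0) stop("'features' must be nonempty")
  labels <- phenoLabels(pset)
  if (is.null(labels)) stop("labels required")
  absent <- setdiff(features, featureIds(pset))
  if (length(absent))
    stop("required feature(s) absent from data: ",
         paste(absent, collapse = ", "))
  x <- traitTable(pset)[, features, drop = FALSE]
  y <- factor(labels, levels = sort(unique(labels)))
  p <- length(features)
  mtryDefault <- max(1L, floor(sqrt(p)))
  set.seed(seed)
  s1 <- .tuneStage(x, y, as.integer(ntreeGrid), nRepeats,
                   fixed = list(mtry = mtryDefault), stage = "ntree")
  ntreeStar <- s1$value
  mtryGrid <- seq_len(min(15L, as.integer(ceiling(sqrt(p))) + 10L, p))
  s2 <- .tuneStage(x, y, mtryGrid, nRepeats,
                   fixed = list(ntree = ntreeStar), stage = "mtry")
  mtryStar <- s2$value
  final <- randomForest::randomForest(x = x, y = y, ntree = ntreeStar,
                                      mtry = mtryStar, keep.forest = TRUE)
  levelsMap <- lapply(x, function(col)
    list(levels = levels(col), mode = .featureMode(as.character(col))))
  new("ForestModel", ntree = as.integer(ntreeStar),
      mtry = as.integer(mtryStar), features = features,
      levelsMap = levelsMap, classLevels = levels(y), forest = final,
      oobError = unname(final$err.rate[ntreeStar, "OOB"]),
      tuning = rbind(s1$table, s2$table))
}

#' Boruta selection followed by forest tuning
#'
#' The full random-forest training protocol: [borutaSelect()] confirms the
#' relevant features, then [tuneForest()] tunes ntree and mtry on the
#' confirmed set and fits the final forest.
#'
#' @inheritParams borutaSelect
#' @param ... passed on to [tuneForest()].
#' @return a [ForestModel-class]; the [BorutaResult-class] is attached in
#'   the `"boruta"` attribute.
#' @export
fitForest <- function(pset, ntree = 500L, maxRuns = 100L, pThreshold = 0.01,
                      seed = 1L, ...) {
  sel <- borutaSelect(pset, ntree = ntree, maxRuns = maxRuns,
                      pThreshold = pThreshold, seed = seed)
  if (length(sel@confirmed) == 0)
    stop("Boruta confirmed no features; cannot fit a forest")
  model <- tuneForest(pset, features = sel@confirmed, seed = seed + 1L, ...)
  attr(model, "boruta") <- sel
  model
}

#' @rdname predictProba
setMethod("predictProba", "ForestModel", function(object, newdata, ...) {
  absent <- setdiff(object@features, featureIds(newdata))
  if (length(absent))
    stop("required feature(s) absent from data: ",
         paste(absent, collapse = ", "))
  m <- traitMatrix(newdata)[, object@features, drop = FALSE]
  nd <- as.data.frame(m, stringsAsFactors = FALSE, optional = TRUE)
  for (f in object@features) {
    lm <- object@levelsMap[[f]]
    v <- factor(m[, f], levels = lm$levels)
    v[is.na(v)] <- lm$mode  # unseen levels fall back to the training mode
    nd[[f]] <- v
  }
  pr <- predict(object@forest, newdata = nd, type = "prob")
  pr <- pr[, object@classLevels, drop = FALSE]
  rownames(pr) <- rownames(m)
  pr
})
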