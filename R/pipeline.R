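# Orchestration of the full analysis: simulate -> preprocess ->
# dissimilarity -> cluster / savannah / mds -> train (x3) -> evaluate ->
# cross-cohort -> two-stage, writing every artifact plus a manifest that
# records package/R versions, all seeds and parameters, and the MD5 of every
# output, so a run is reproducible from the manifest alone.

.PIPELINE_STAGES <- c("simulate", "preprocess", "dissimilarity", "cluster",
                      "savannah", "mds", "train", "evaluate", "crosscohort",
                      "twostage")

#' Assemble a pipeline configuration
#'
#' @param outDir output directory (created if needed).
#' @param stages subset of the pipeline stages to write outputs for;
#'   prerequisites of a requested stage are computed in memory as needed.
#' @param spec a [CohortSpec-class] (default: [cohortSpec()] at `seed`).
#' @param seed master seed for every downstream stage.
#' @param ntree forest size for the dissimilarity (default 10000).
#' @param savannahNtree,nPermutations Savannah-stage forest size and
#'   replicate count.
#' @param kmin,kmax cluster-number range.
#' @param trainFraction training fraction of the 90/10 split.
#' @param methods supervised methods to fit.
#' @param missingRate missingness injected after simulation (defaults to the
#'   spec's rate).
#' @return a validated config list of class `"prakritiPipelineConfig"`.
#' @export
pipelineConfig <- function(outDir, stages = .PIPELINE_STAGES,
                           spec = NULL, seed = 1L, ntree = 10000L,
                           savannahNtree = 2000L, nPermutations = 20L,
                           kmin = 2L, kmax = 20L, trainFraction = 0.9,
                           methods = c("lasso", "enet", "rf"),
                           missingRate = NULL) {
  stages <- match.arg(stages, .PIPELINE_STAGES, several.ok = TRUE)
  if (is.null(spec)) spec <- cohortSpec(seed = seed)
  structure(list(outDir = outDir, stages = stages, spec = spec,
                 seed = as.integer(seed), ntree = as.integer(ntree),
                 savannahNtree = as.integer(savannahNtree),
                 nPermutations = as.integer(nPermutations),
                 kmin = as.integer(kmin), kmax = as.integer(kmax),
                 trainFraction = trainFraction, methods = methods,
                 missingRate = if (is.null(missingRate)) spec@missingRate
                               else missingRate),
            class = "prakritiPipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages on a simulated cohort pair and writes every
#' artifact (TSV matrices, JSON reports) under `config$outDir`.  A stage
#' failure aborts with the stage name and leaves a `<stage>.partial` marker.
#'
#' @param config a config from [pipelineConfig()].
#' @param quiet suppress progress messages.
#' @return the manifest list, invisibly (also written as `manifest.json`).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "prakritiPipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[", ..., "]")
  outputs <- character(0)
  emit <- function(name) outputs <<- c(outputs, file.path(config$outDir, name))
  cache <- new.env(parent = emptyenv())
  need <- function(key, fn) {
    if (!exists(key, cache)) assign(key, fn(), cache)
    get(key, cache)
  }
  stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    say(name)
    marker <- file.path(config$outDir, paste0(name, ".partial"))
    file.create(marker)
    # the marker survives a failure, flagging partial outputs
    tryCatch({ fn(); unlink(marker) }, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  spec <- config$spec
  seed <- config$seed
  getRaw <- function() need("raw", function() {
    ext <- generateExtreme(spec)
    if (config$missingRate > 0)
      ext <- injectMissing(ext, config$missingRate, seed = spec@seed + 3L)
    ext
  })
  getNonExtreme <- function() need("nonextreme", function()
    generateNonExtreme(spec))
  getCohortB <- function() need("cohortB", function()
    deriveSecondCohort(spec,
                       sharedFeatures = min(106L, spec@nFeatures)))
  getClean <- function() need("clean", function()
    preprocessPhenotypes(getRaw()))
  getDiss <- function() need("diss", function()
    rfDissimilarity(getClean()$data, ntree = config$ntree, seed = seed))
  getModels <- function() need("models", function() {
    split <- splitTrainTest(getClean()$data,
                            fraction = config$trainFraction, seed = seed)
    models <- list()
    for (m in config$methods)
      models[[m]] <- switch(m, lasso = fitLasso(split$train, seed = seed),
                            enet = fitEnet(split$train, seed = seed),
                            rf = fitForest(split$train, seed = seed))
    list(split = split, models = models)
  })

  stage("simulate", function() {
    writePhenotypeTSV(getRaw(), file.path(config$outDir, "cohortA.tsv"))
    writePhenotypeTSV(getNonExtreme(),
                      file.path(config$outDir, "nonextreme.tsv"))
    writePhenotypeTSV(getCohortB(), file.path(config$outDir, "cohortB.tsv"))
    writeCohortSpec(spec, file.path(config$outDir, "spec.yaml"))
    emit("cohortA.tsv"); emit("nonextreme.tsv"); emit("cohortB.tsv")
    emit("spec.yaml")
  })
  stage("preprocess", function() {
    pp <- getClean()
    writePhenotypeTSV(pp$data, file.path(config$outDir, "clean.tsv"))
    r <- pp$report
    jsonlite::write_json(
      list(removed_missing = r@removedMissing,
           removed_nonvarying = r@removedNonVarying,
           imputed = r@imputed, n_features_in = r@nFeaturesIn,
           n_features_out = r@nFeaturesOut),
      file.path(config$outDir, "preprocess_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("clean.tsv"); emit("preprocess_report.json")
  })
  stage("dissimilarity", function() {
    writeDissimilarityTSV(getDiss(), file.path(config$outDir, "dist.tsv"))
    emit("dist.tsv")
  })
  stage("cluster", function() {
    sel <- selectK(getDiss(), config$kmin,
                   min(config$kmax, length(sampleIds(getClean()$data)) - 1L))
    sol <- sel$solutions[[as.character(sel$kStar)]]
    agreement <- clusterLabelAgreement(sol@assignment,
                                       phenoLabels(getClean()$data))
    jsonlite::write_json(
      list(k_star = sel$kStar, widths = as.list(sel$widths),
           agreement = agreement, medoids = sol@medoids,
           assignment = as.list(sol@assignment)),
      file.path(config$outDir, "clusters.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("clusters.json")
  })
  stage("savannah", function() {
    sv <- savannah(getClean()$data, ntree = config$savannahNtree,
                   nPermutations = config$nPermutations, kmin = config$kmin,
                   kmax = min(config$kmax,
                              length(sampleIds(getClean()$data)) - 1L),
                   seed = seed)
    writeSavannahTSV(sv, file.path(config$outDir, "savannah.tsv"))
    emit("savannah.tsv")
  })
  stage("mds", function() {
    coords <- classicalMDS(getDiss())
    write.table(data.frame(sample_id = rownames(coords), coords,
                           label = phenoLabels(getClean()$data)),
                file.path(config$outDir, "coords.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("coords.tsv")
  })
  stage("train", function() {
    tm <- getModels()
    summ <- lapply(tm$models, function(m)
      list(selected_features = selectedFeatures(m)))
    jsonlite::write_json(summ, file.path(config$outDir, "models.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("models.json")
  })
  stage("evaluate", function() {
    tm <- getModels()
    for (m in names(tm$models)) {
      rep <- evaluateModel(tm$models[[m]], tm$split$test)
      writeEvalReportJSON(rep, file.path(config$outDir,
                                         paste0("eval_", m, ".json")))
      emit(paste0("eval_", m, ".json"))
    }
  })
  stage("crosscohort", function() {
    cleanB <- preprocessPhenotypes(getCohortB())$data
    for (m in config$methods) {
      xv <- crossCohortValidate(getClean()$data, cleanB, method = m,
                                seed = seed)
      writeEvalReportJSON(xv$report, file.path(config$outDir,
                                               paste0("xval_", m, ".json")))
      emit(paste0("xval_", m, ".json"))
    }
  })
  stage("twostage", function() {
    tm <- getModels()
    ts <- twoStageClassifier(tm$models, getClean()$data, getNonExtreme(),
                             seed = seed)
    out <- lapply(ts, function(r)
      list(sensitivity = r$sensitivity, specificity = r$specificity,
           auc = r$auc, mean_cv_accuracy = mean(r$model@cvAccuracies),
           intercept = r$model@intercept, slope = r$model@slope))
    jsonlite::write_json(out, file.path(config$outDir, "twostage.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    scoresTab <- do.call(rbind, lapply(ts, function(r)
      data.frame(method = r$scores@sourceMethod,
                 sample_id = r$scores@sampleIds, score = r$scores@score,
                 is_extreme = r$scores@isExtreme)))
    write.table(scoresTab, file.path(config$outDir, "twostage_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    emit("twostage.json"); emit("twostage_scores.tsv")
  })

  manifest <- list(
    package = "PrakritiML",
    version = as.character(packageVersion("PrakritiML")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    stages = config$stages, seed = seed,
    parameters = list(ntree = config$ntree,
                      savannahNtree = config$savannahNtree,
                      nPermutations = config$nPermutations,
                      kmin = config$kmin, kmax = config$kmax,
                      trainFraction = config$trainFraction,
                      methods = config$methods,
                      missingRate = config$missingRate),
    spec = .specAsList(config$spec),
    outputs = lapply(setNames(outputs, basename(outputs)),
                     function(f) unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
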