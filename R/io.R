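# Plain-text serialization: TSV for matrices, JSON for reports, YAML/JSON for
# cohort specifications.  The missing marker in phenotype TSVs is the literal
# string NA.

#' Write a PhenotypeSet as TSV
#'
#' Columns: `sample_id`, then `label` when labels are present, then one
#' column per feature; missing cells are written as `NA`.
#'
#' @param pset a [PhenotypeSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePhenotypeTSV <- function(pset, path) {
  m <- traitMatrix(pset)
  df <- data.frame(sample_id = rownames(m), stringsAsFactors = FALSE)
  lab <- phenoLabels(pset)
  if (!is.null(lab)) df$label <- lab
  df <- cbind(df, as.data.frame(m, stringsAsFactors = FALSE,
                                optional = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a PhenotypeSet from TSV
#'
#' @param path TSV with a `sample_id` column, an optional `label` column and
#'   one column per feature; `NA` marks missing.
#' @return a [PhenotypeSet-class].
#' @export
readPhenotypeTSV <- function(path) {
  df <- read.delim(path, sep = "\t", colClasses = "character",
                   na.strings = "NA", check.names = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("missing 'sample_id' column")
  ids <- df$sample_id
  labels <- if ("label" %in% colnames(df)) df$label else NULL
  feats <- setdiff(colnames(df), c("sample_id", "label"))
  m <- as.matrix(df[, feats, drop = FALSE])
  rownames(m) <- ids
  PhenotypeSet(m, labels = labels)
}

#' Write / read a DissimilarityMatrix as TSV
#'
#' Square layout with a `sample_id` header column.
#' @param D a [DissimilarityMatrix-class].
#' @param path file path.
#' @return `path` (write) or a [DissimilarityMatrix-class] (read).
#' @export
writeDissimilarityTSV <- function(D, path) {
  d <- dissMatrix(D)
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDissimilarityTSV
#' @export
readDissimilarityTSV <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  ids <- df$sample_id
  d <- as.matrix(df[, -1, drop = FALSE])
  dimnames(d) <- list(ids, ids)
  DissimilarityMatrix(d)
}

#' Write a Savannah run as long-format TSV
#'
#' Rows are (replicate, k, width); replicate 0 is the original data —
#' plot-ready for a Savannah-style figure.
#'
#' @param x a [SavannahResult-class].
#' @param path output file.
#' @export
writeSavannahTSV <- function(x, path) {
  write.table(savannahTable(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Serialize an EvalReport as JSON
#'
#' Mirrors the per-class summary-table shape: sensitivity and specificity in
#' percent per class, the confusion matrix, and the overall accuracy.
#'
#' @param report an [EvalReport-class].
#' @param path output file.
#' @export
writeEvalReportJSON <- function(report, path) {
  out <- list(
    accuracy_pct = 100 * report@accuracy,
    sensitivity_pct = as.list(round(100 * report@sensitivity, 2)),
    specificity_pct = as.list(round(100 * report@specificity, 2)),
    confusion = list(classes = rownames(report@confusion),
                     counts = unname(apply(report@confusion, 1, as.list))))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.specAsList <- function(spec) {
  list(classNames = spec@classNames, nPerClass = spec@nPerClass,
       nNonExtreme = as.list(setNames(as.integer(spec@nNonExtreme),
                                      names(spec@nNonExtreme))),
       nFeatures = spec@nFeatures, nInformative = spec@nInformative,
       levelsPerFeature = spec@levelsPerFeature,
       signalStrength = spec@signalStrength, nBlocks = spec@nBlocks,
       blockCoupling = spec@blockCoupling, missingRate = spec@missingRate,
       seed = spec@seed)
}

#' Write / read a CohortSpec as YAML (or JSON by extension)
#'
#' @param spec a [CohortSpec-class].
#' @param path file ending in `.yaml`/`.yml` or `.json`.
#' @return `path` (write) or a [CohortSpec-class] (read).
#' @export
writeCohortSpec <- function(spec, path) {
  lst <- .specAsList(spec)
  if (grepl("\\.json$", path))
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname writeCohortSpec
#' @export
readCohortSpec <- function(path) {
  lst <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cohortSpec(classNames = lst$classNames, nPerClass = lst$nPerClass,
             nNonExtreme = unlist(lst$nNonExtreme),
             nFeatures = lst$nFeatures, nInformative = lst$nInformative,
             levelsPerFeature = lst$levelsPerFeature,
             signalStrength = lst$signalStrength, nBlocks = lst$nBlocks,
             blockCoupling = lst$blockCoupling,
             missingRate = lst$missingRate, seed = lst$seed)
}
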