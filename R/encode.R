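# Dummy (one-hot minus reference) coding of categorical traits for the
# penalized multinomial models.

#' Dummy-code a categorical trait table
#'
#' Builds one 0/1 indicator column per non-reference level per feature.  The
#' reference level is the feature's most frequent level, ties broken
#' lexicographically, so for each feature a sample either sets exactly one of
#' that feature's columns or none (reference level).
#'
#' @param pset a preprocessed [PhenotypeSet-class] (no missing values, no
#'   constant features).
#' @return an [EncodedDesign-class].
#' @export
encodeDesign <- function(pset) {
  m <- traitMatrix(pset)
  if (anyNA(m)) stop("missing values present; preprocess first")
  encoding <- vector("list", ncol(m))
  names(encoding) <- colnames(m)
  for (j in seq_len(ncol(m))) {
    levs <- sort(unique(m[, j]))
    if (length(levs) < 2)
      stop("feature '", colnames(m)[j], "' is constant; preprocess first")
    encoding[[j]] <- list(levels = levs, ref = .featureMode(m[, j]))
  }
  enc <- encodeWithScheme(encoding, pset)
  enc
}

#' Encode a PhenotypeSet under a fixed coding scheme
#'
#' Applies a training-data encoding to (possibly new) data: indicator columns
#' are exactly those of the scheme, levels unseen at training time score as
#' the reference (all indicators zero), and a missing required feature raises
#' an error naming it.
#'
#' @param encoding per-feature scheme as stored in
#'   [EncodedDesign-class]`@encoding`.
#' @param pset a [PhenotypeSet-class] containing the scheme's features.
#' @return an [EncodedDesign-class].
#' @export
encodeWithScheme <- function(encoding, pset) {
  m <- traitMatrix(pset)
  absent <- setdiff(names(encoding), colnames(m))
  if (length(absent))
    stop("required feature(s) absent from data: ",
         paste(absent, collapse = ", "))
  cols <- list()
  parent <- character()
  for (f in names(encoding)) {
    nonref <- setdiff(encoding[[f]]$levels, encoding[[f]]$ref)
    for (lev in nonref) {
      cname <- paste0(f, "=", lev)
      cols[[cname]] <- as.numeric(m[, f] == lev)
      parent[cname] <- f
    }
  }
  X <- do.call(cbind, cols)
  rownames(X) <- rownames(m)
  new("EncodedDesign", X = X, parent = parent, encoding = encoding)
}
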