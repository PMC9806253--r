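#' Stability filtering of radiomic features against repeat segmentations
#'
#' For every feature, the single-rater absolute-agreement ICC(2,1) is
#' computed across the paired re-segmentation subset (original vs repeat
#' segmentation of the same patients); features with ICC below the
#' threshold are flagged unstable.
#'
#' @param X numeric matrix, patients x features (original segmentation),
#'   rows named by patient id.
#' @param Xrepeat numeric matrix for the re-segmented subset, patients x
#'   features, rows named by patient id (these patients must be present in
#'   `X`), with the same feature columns.
#' @param threshold ICC retention threshold (default 0.8).
#' @return A data.frame with columns `feature`, `icc`, `stable`.
#' @export
filterStable <- function(X, Xrepeat, threshold = 0.8) {
  miss <- setdiff(colnames(X), colnames(Xrepeat))
  if (length(miss))
    stop("features missing from the paired table: ",
         paste(head(miss, 5), collapse = ", "))
  ids <- rownames(Xrepeat)
  if (is.null(ids) || !all(ids %in% rownames(X)))
    stop("re-segmented patients must be a subset of the primary table")
  A <- X[ids, colnames(X), drop = FALSE]
  B <- Xrepeat[, colnames(X), drop = FALSE]
  icc <- vapply(seq_len(ncol(A)), function(j) {
    suppressWarnings(icc2wayRandom(cbind(A[, j], B[, j])))
  }, 0)
  data.frame(feature = colnames(X), icc = icc, stable = icc >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank stable features by univariate discriminative AUC
#'
#' Computes the per-feature AUC against a binary endpoint on the training
#' cohort and keeps the `min(topK, n)` most discriminative features. By
#' default ranking is direction-agnostic (`max(AUC, 1 - AUC)`), since a
#' feature with AUC 0.1 is highly informative; set
#' `directionAgnostic = FALSE` to rank by the literal AUC. Ties are broken
#' lexicographically on feature name for determinism.
#'
#' @param X numeric matrix, patients x features (training cohort only).
#' @param labels binary endpoint for the same patients.
#' @param topK selection size cap (default 50).
#' @param directionAgnostic rank by `max(AUC, 1 - AUC)` (default TRUE).
#' @return A data.frame with columns `feature`, `auc`, `discrimination`,
#'   ordered by decreasing discrimination.
#' @export
rankByAuc <- function(X, labels, topK = 50, directionAgnostic = TRUE) {
  y <- asBinary(labels)
  if (all(y) || !any(y)) stop("labels contain a single class")
  auc <- vapply(seq_len(ncol(X)), function(j) rocAuc(X[, j], y), 0)
  disc <- if (directionAgnostic) pmax(auc, 1 - auc) else auc
  nm <- colnames(X)
  ord <- order(-disc, nm)
  keep <- head(ord, min(topK, ncol(X)))
  data.frame(feature = nm[keep], auc = auc[keep],
             discrimination = disc[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}
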