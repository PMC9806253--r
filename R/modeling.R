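#' Split a cohort into training and validation sets
#'
#' Random, reproducible split at the given ratio (default 3:1), with the
#' training size rounded up (`ceiling(0.75 n)` for 3:1, so 182 patients
#' give the 137/45 split). With `stratify`, per-class training counts are
#' allocated by largest remainder so each class ratio is within one patient
#' of the target.
#'
#' @param ids character or integer patient identifiers.
#' @param ratio numeric(2), training:validation proportions (default `c(3, 1)`).
#' @param seed integer seed; the same seed always yields the same split.
#' @param stratify optional class labels aligned with `ids`.
#' @return A list with elements `training`, `validation`, `seed`.
#' @export
splitCohort <- function(ids, ratio = c(3, 1), seed = 1, stratify = NULL) {
  n <- length(ids)
  frac <- ratio[1] / sum(ratio)
  nTrain <- ceiling(frac * n)
  if (n < 8 || nTrain < 1 || nTrain >= n)
    stop("ratio infeasible for a cohort of ", n)
  set.seed(seed)
  if (is.null(stratify)) {
    tr <- sample(ids, nTrain)
  } else {
    g <- factor(stratify)
    target <- frac * table(g)
    base <- floor(target)
    rem <- nTrain - sum(base)
    if (rem > 0) {
      extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    tr <- unlist(lapply(levels(g), function(cl) {
      sample(ids[g == cl], base[[cl]])
    }), use.names = FALSE)
  }
  list(training = sort(tr), validation = sort(setdiff(ids, tr)), seed = seed)
}

stratifiedFolds <- function(y, nfolds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

#' Fit a LASSO radiomic score model
#'
#' L1-penalized logistic regression over a lambda path with stratified,
#' seeded 5-fold cross-validation; the penalty with the minimum mean CV
#' deviance is selected and the features with nonzero coefficients become
#' the model. Inputs are standardized to training mean 0 / sd 1 before
#' penalization and the standardization parameters are stored, so the score
#' `beta_0 + sum_j beta_j x~_j` is reproducible from the fitted object
#' alone.
#'
#' @param X numeric matrix, patients x features, with column names.
#' @param labels binary endpoint (TRUE / second factor level = positive).
#' @param nfolds CV folds (default 5; reduced if a class is smaller).
#' @param seed integer seed for the fold assignment.
#' @param endpoint,roi,source metadata stored on the model.
#' @return A [RadiomicModel-class].
#' @export
fitLassoModel <- function(X, labels, nfolds = 5, seed = 1,
                          endpoint = "inflamed_vs_noninflamed",
                          roi = "whole", source = "RFG") {
  y <- asBinary(labels)
  if (all(y) || !any(y)) stop("both classes must be present")
  if (is.null(colnames(X))) stop("X must have feature column names")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  nfolds <- min(nfolds, sum(y), sum(!y))
  fold <- stratifiedFolds(y, nfolds, seed)
  # glmnet warns when late (small) lambdas hit maxit = 1e4; those lambdas
  # lie far past lambda.min here, so the warning is noise for this use
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(Xs, y, family = "binomial", alpha = 1,
                      maxit = 1e4, foldid = fold, standardize = FALSE,
                      type.measure = "deviance"),
    warning = function(w) {
      if (grepl("maxit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  lambda <- cv$lambda.min
  cf <- as.numeric(coef(cv, s = lambda))
  names(cf) <- rownames(coef(cv, s = lambda))
  beta <- cf[-1]
  sel <- beta[beta != 0]
  if (length(sel) == 0) {
    # minimum-CV-error penalty kept the null model (weak endpoint); step
    # down to the largest penalty on the path that admits >= 1 feature
    nz <- cv$nzero > 0
    if (!any(nz))
      stop("degenerate path: all coefficients are zero at every lambda")
    lambda <- max(cv$lambda[nz])
    cf <- as.numeric(coef(cv, s = lambda))
    names(cf) <- rownames(coef(cv, s = lambda))
    beta <- cf[-1]
    sel <- beta[beta != 0]
    if (length(sel) == 0)
      stop("degenerate path: all coefficients are zero at lambda.min")
  }
  new("RadiomicModel", endpoint = endpoint, roi = roi, source = source,
      features = names(sel), coefficients = sel, intercept = cf[[1]],
      lambda = lambda, center = ctr[names(sel)],
      scale = scl[names(sel)], cutoff = NA_real_, submodels = list())
}

# assemble the model's input matrix from a patients-x-features matrix or a
# SummarizedExperiment whose assays are features x patients; tagged feature
# names ("assay:feature") index into the corresponding assay
modelInputs <- function(model, data) {
  feats <- model@features
  if (length(model@submodels)) {
    sc <- vapply(model@submodels, predictScore, numeric(ncolData(data)),
                 data = data)
    colnames(sc) <- names(model@submodels)
    return(sc[, feats, drop = FALSE])
  }
  if (is(data, "SummarizedExperiment")) {
    parts <- strsplit(feats, ":", fixed = TRUE)
    X <- vapply(parts, function(pf) {
      if (length(pf) != 2L)
        stop("feature '", paste(pf, collapse = ":"),
             "' is not assay-tagged; supply a feature matrix instead")
      a <- SummarizedExperiment::assay(data, pf[1])
      if (!pf[2] %in% rownames(a)) stop("missing feature: ", pf[2])
      a[pf[2], ]
    }, numeric(ncol(data)))
    X <- matrix(X, ncol = length(feats),
                dimnames = list(colnames(data), feats))
    return(X)
  }
  miss <- setdiff(feats, colnames(data))
  if (length(miss))
    stop("missing features: ", paste(head(miss, 5), collapse = ", "))
  as.matrix(data[, feats, drop = FALSE])
}

ncolData <- function(data)
  if (is(data, "SummarizedExperiment")) ncol(data) else nrow(data)

#' Compute the radiomic score of a fitted model
#'
#' @param model a [RadiomicModel-class].
#' @param data a patients x features matrix containing the model's features,
#'   or a `SummarizedExperiment` of RFG assays (features x patients) when
#'   the model's features are assay-tagged.
#' @return Numeric score per patient.
#' @export
predictScore <- function(model, data) {
  X <- modelInputs(model, data)
  Xs <- scale(X, center = model@center[colnames(X)],
              scale = model@scale[colnames(X)])
  drop(model@intercept + Xs %*% model@coefficients[colnames(X)])
}

#' Score-combined (SC) fusion of per-phase radiomic models
#'
#' Refits the LASSO (same settings) on the per-phase model scores as a
#' 4-dimensional input; the nested per-phase models are stored so the
#' combined model scores end to end from raw features.
#'
#' @param models named list of per-phase [RadiomicModel-class] objects
#'   (at least 2) for the same endpoint/ROI.
#' @param data training data (matrix or `SummarizedExperiment`).
#' @param labels binary endpoint for the training patients.
#' @param nfolds,seed CV settings passed to [fitLassoModel()].
#' @return A [RadiomicModel-class] with `source = "SC"`.
#' @export
combineScores <- function(models, data, labels, nfolds = 5, seed = 1) {
  if (length(models) < 2) stop("need at least two phase models to combine")
  if (is.null(names(models)))
    names(models) <- paste0("RFG", seq_along(models))
  sc <- vapply(models, predictScore, numeric(ncolData(data)), data = data)
  colnames(sc) <- paste0("score:", names(models))
  m0 <- models[[1]]
  fit <- fitLassoModel(sc, labels, nfolds = nfolds, seed = seed,
                       endpoint = m0@endpoint, roi = m0@roi, source = "SC")
  fit@submodels <- setNames(models, paste0("score:", names(models)))
  validObject(fit)
  fit
}

#' Feature-combined (FC) fusion of per-phase radiomic models
#'
#' Pools the features selected by the per-phase models (union of their
#' assay-tagged names) and refits the LASSO on the pooled set with the same
#' cross-validation protocol.
#'
#' @inheritParams combineScores
#' @return A [RadiomicModel-class] with `source = "FC"`.
#' @export
combineFeatures <- function(models, data, labels, nfolds = 5, seed = 1) {
  pooled <- unique(unlist(lapply(models, function(m) m@features)))
  if (length(pooled) == 0) stop("empty pooled feature set")
  proxy <- new("RadiomicModel", endpoint = models[[1]]@endpoint,
               roi = models[[1]]@roi, source = "FC", features = pooled,
               coefficients = setNames(rep(1, length(pooled)), pooled),
               intercept = 0, lambda = 1,
               center = setNames(rep(0, length(pooled)), pooled),
               scale = setNames(rep(1, length(pooled)), pooled))
  X <- modelInputs(proxy, data)
  fitLassoModel(X, labels, nfolds = nfolds, seed = seed,
                endpoint = models[[1]]@endpoint, roi = models[[1]]@roi,
                source = "FC")
}

#' Youden-optimal score cutoff
#'
#' The threshold maximizing sensitivity + specificity, searched over the
#' midpoints of consecutive sorted unique scores (positive call when
#' score >= cutoff); ties resolve to the lowest such threshold.
#'
#' @param scores numeric scores.
#' @param labels binary outcome.
#' @return The optimal cutoff value.
#' @export
optimalCutoff <- function(scores, labels) {
  y <- asBinary(labels)
  if (all(y) || !any(y)) stop("both classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  j <- vapply(cand, function(t) {
    mean(scores[y] >= t) + mean(scores[!y] < t)
  }, 0)
  cand[which.max(j)]
}

#' Two-stage three-class immunophenotype call
#'
#' Cascades the two cutoff-thresholded scores: a whole-tumor score at or
#' above its cutoff calls "inflamed"; otherwise a peripheral score at or
#' above its cutoff calls "excluded", else "desert". Orientation: a higher
#' whole-tumor score indicates the inflamed phenotype (positive correlation
#' with central CD8+ density) and a higher peripheral score the excluded
#' phenotype.
#'
#' @param wholeScore,periScore numeric score vectors (same patients).
#' @param cWhole,cPeri cutoffs fitted on the training cohort.
#' @return Factor with levels desert, excluded, inflamed.
#' @export
callPhenotype <- function(wholeScore, periScore, cWhole, cPeri) {
  out <- ifelse(wholeScore >= cWhole, "inflamed",
                ifelse(periScore >= cPeri, "excluded", "desert"))
  factor(out, levels = c("desert", "excluded", "inflamed"))
}

#' Evaluate three-class phenotype calls
#'
#' @param calls factor of predicted phenotypes.
#' @param truth factor of true phenotypes (same levels).
#' @return A list with `confusion` (rows = truth), `accuracy`, `f1`
#'   (per class) and `macroF1`.
#' @export
evaluateCalls <- function(calls, truth) {
  if (length(calls) != length(truth)) stop("label length mismatch")
  if (length(calls) == 0) stop("empty input")
  lev <- union(levels(factor(truth)), levels(factor(calls)))
  truth <- factor(truth, levels = lev)
  calls <- factor(calls, levels = lev)
  cm <- table(truth = truth, called = calls)
  acc <- sum(diag(cm)) / sum(cm)
  f1 <- vapply(seq_along(lev), function(i) {
    tp <- cm[i, i]; fp <- sum(cm[-i, i]); fn <- sum(cm[i, -i])
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  names(f1) <- lev
  list(confusion = cm, accuracy = acc, f1 = f1,
       macroF1 = mean(f1, na.rm = TRUE))
}

modelToList <- function(model) {
  list(endpoint = model@endpoint, roi = model@roi, source = model@source,
       features = model@features,
       coefficients = as.list(model@coefficients),
       intercept = model@intercept, lambda = model@lambda,
       center = as.list(model@center), scale = as.list(model@scale),
       cutoff = model@cutoff,
       submodels = lapply(model@submodels, modelToList))
}

modelFromList <- function(x) {
  new("RadiomicModel", endpoint = x$endpoint, roi = x$roi, source = x$source,
      features = unlist(x$features),
      coefficients = unlist(x$coefficients),
      intercept = x$intercept, lambda = x$lambda,
      center = unlist(x$center), scale = unlist(x$scale),
      cutoff = if (is.null(x$cutoff)) NA_real_ else as.numeric(x$cutoff),
      submodels = lapply(x$submodels, modelFromList))
}

#' Serialize a radiomic model to JSON
#'
#' Coefficients and standardization parameters are written with 17
#' significant digits so reloaded models reproduce scores exactly.
#'
#' @param model a [RadiomicModel-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeModelJson <- function(model, path) {
  jsonlite::write_json(modelToList(model), path, auto_unbox = TRUE,
                       digits = I(17), null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Load a radiomic model from JSON
#'
#' @param path file written by [writeModelJson()].
#' @return A [RadiomicModel-class].
#' @export
readModelJson <- function(path) {
  modelFromList(jsonlite::read_json(path, simplifyVector = FALSE))
}
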