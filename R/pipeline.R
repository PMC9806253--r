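RFG_PHASES <- paste0("dce", 1:4)

# one patient, one phase: the 833-feature RFG per requested ROI, sharing a
# single wavelet filter bank between ROIs (identical values to extractRFG,
# which recomputes the bank per ROI)
extractPhaseRFGs <- function(v, rois, nLevels, rimMm) {
  pad <- max(vapply(WAVELET_FILTERS, function(f) length(f$dec_lo), 0L))
  v <- cropToMask(v, pad = pad)
  rimMask <- if ("peri" %in% rois) peripheralRim(v, rimMm)@mask else NULL
  bank <- filterBank(v)
  # texture matrices only see in-mask voxels, so the scans can run on the
  # tight mask bounding box; wavelet filtering above used the padded box
  idx <- which(v@mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min); hi <- apply(idx, 2, max)
  tighten <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  tightMask <- tighten(v@mask)
  tightImages <- c(list(orig = tighten(v@intensities)),
                   lapply(bank, function(w) tighten(w@intensities)))
  names(tightImages) <- c("orig", paste0("wav_", names(bank)))
  out <- list()
  for (roi in rois) {
    msk <- if (roi == "peri") tighten(rimMask) else tightMask
    feats <- lapply(names(tightImages), function(nm) {
      f <- textureFeatures(VolumeWithMask(tightImages[[nm]], v@spacing, msk),
                           nLevels)
      names(f) <- paste0(nm, "_", names(f))
      f
    })
    out[[roi]] <- c(volume_mm3 = sum(msk) * prod(v@spacing), unlist(feats))
  }
  out
}

#' Extract all radiomic feature groups of a cohort
#'
#' Computes the 833-feature RFG for every patient, DCE phase and ROI, and
#' returns them as a `SummarizedExperiment` with one assay per RFG
#' (features x patients; assays `whole_1..whole_4`, `peri_1..peri_4`).
#' Phenotype labels and CD8+ densities go into `colData`. When the cohort
#' contains second-rater segmentations, the matching re-segmented RFGs are
#' stored in `metadata(se)$resegmented` for stability filtering.
#'
#' @param cohort a [SyntheticCohort-class] (or any list of
#'   [SyntheticPatient-class] objects).
#' @param nLevels gray levels for discretization (default 32).
#' @param rimMm rim thickness in mm (default 2).
#' @param rois ROIs to extract (default both `"whole"` and `"peri"`).
#' @return A `SummarizedExperiment`.
#' @export
extractCohortFeatures <- function(cohort, nLevels = 32, rimMm = 2,
                                  rois = c("whole", "peri")) {
  patients <- if (is(cohort, "SyntheticCohort")) cohort@patients else cohort
  ids <- vapply(patients, slot, "", "id")
  assayNames <- unlist(lapply(rois, function(r) paste0(r, "_", 1:4)))
  assays <- lapply(assayNames, function(a) {
    matrix(NA_real_, 833, length(ids), dimnames = list(NULL, ids))
  })
  names(assays) <- assayNames
  resegIds <- ids[vapply(patients, function(p) is.array(p@secondMask), NA)]
  reseg <- lapply(assayNames, function(a)
    matrix(NA_real_, 833, length(resegIds), dimnames = list(NULL, resegIds)))
  names(reseg) <- assayNames
  featNames <- NULL
  for (i in seq_along(patients)) {
    pt <- patients[[i]]
    for (p in 1:4) {
      rfgs <- extractPhaseRFGs(phaseVolume(pt, RFG_PHASES[p]), rois,
                               nLevels, rimMm)
      for (roi in rois) {
        a <- paste0(roi, "_", p)
        if (is.null(rownames(assays[[a]]))) {
          featNames <- names(rfgs[[roi]])
          rownames(assays[[a]]) <- featNames
          rownames(reseg[[a]]) <- featNames
        }
        assays[[a]][, ids[i]] <- rfgs[[roi]]
      }
    }
    if (ids[i] %in% resegIds) {
      for (p in 1:4) {
        rfgs <- extractPhaseRFGs(phaseVolume(pt, RFG_PHASES[p],
                                             useSecondMask = TRUE),
                                 rois, nLevels, rimMm)
        for (roi in rois)
          reseg[[paste0(roi, "_", p)]][, ids[i]] <- rfgs[[roi]]
      }
    }
  }
  cd8 <- t(vapply(patients, slot, numeric(2), "cd8"))
  cd <- S4Vectors::DataFrame(
    phenotype = factor(vapply(patients, slot, "", "phenotype"),
                       levels = PHENOTYPES),
    cd8_central = cd8[, 1], cd8_peripheral = cd8[, 2], row.names = ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = cd,
    metadata = list(settings = list(nLevels = nLevels, rimMm = rimMm,
                                    rois = rois),
                    resegmented = list(assays = reseg, ids = resegIds)))
}

# patients x features matrix of one assay, columns tagged "assay:feature"
taggedMatrix <- function(assayMat, assayName) {
  X <- t(assayMat)
  colnames(X) <- paste0(assayName, ":", rownames(assayMat))
  X
}

endpointInfo <- function(se, endpoint) {
  phen <- SummarizedExperiment::colData(se)$phenotype
  if (endpoint == "inflamed_vs_noninflamed") {
    list(roi = "whole", ids = colnames(se),
         labels = setNames(phen == "inflamed", colnames(se)))
  } else {
    keep <- phen != "inflamed"
    list(roi = "peri", ids = colnames(se)[keep],
         labels = setNames((phen == "excluded")[keep], colnames(se)[keep]))
  }
}

#' Fit the full set of radiomic models for one endpoint
#'
#' For each of the four phase RFGs of the endpoint's ROI: ICC stability
#' filtering against the re-segmented subset, univariate-AUC top-k ranking
#' on the training patients, and a LASSO score model; then the
#' score-combined (SC) and feature-combined (FC) fusions. All selection and
#' fitting uses training patients only.
#'
#' @param se `SummarizedExperiment` from [extractCohortFeatures()].
#' @param split cohort split from [splitCohort()].
#' @param endpoint `"inflamed_vs_noninflamed"` (whole-tumor ROI) or
#'   `"desert_vs_excluded"` (peripheral ROI).
#' @param topK univariate selection size (default 50).
#' @param iccThreshold ICC stability threshold (default 0.8).
#' @param seed seed for the CV fold assignments.
#' @return A list with `models` (RFG1..RFG4, SC, FC), `labels`, `ids`,
#'   `trainIds`, and the per-model ranked feature sets.
#' @export
fitEndpointModels <- function(se, split, endpoint, topK = 50,
                              iccThreshold = 0.8, seed = 1) {
  info <- endpointInfo(se, endpoint)
  trainIds <- intersect(split$training, info$ids)
  yTrain <- info$labels[trainIds]
  reseg <- S4Vectors::metadata(se)$resegmented
  models <- list()
  ranks <- list()
  for (p in 1:4) {
    a <- paste0(info$roi, "_", p)
    X <- taggedMatrix(SummarizedExperiment::assay(se, a), a)
    Xr <- taggedMatrix(reseg$assays[[a]], a)
    stab <- filterStable(X, Xr, threshold = iccThreshold)
    stableFeats <- stab$feature[stab$stable]
    if (length(stableFeats) == 0)
      stop("no stable features in ", a, " at ICC >= ", iccThreshold)
    rk <- rankByAuc(X[trainIds, stableFeats, drop = FALSE], yTrain,
                    topK = topK)
    ranks[[paste0("RFG", p)]] <- rk
    models[[paste0("RFG", p)]] <-
      fitLassoModel(X[trainIds, rk$feature, drop = FALSE], yTrain,
                    seed = seed + p, endpoint = endpoint, roi = info$roi,
                    source = paste0("RFG", p))
  }
  seTrain <- se[, trainIds]
  models$SC <- combineScores(models[paste0("RFG", 1:4)], seTrain, yTrain,
                             seed = seed + 5)
  models$FC <- combineFeatures(models[paste0("RFG", 1:4)], seTrain, yTrain,
                               seed = seed + 6)
  models$FC@cutoff <- optimalCutoff(predictScore(models$FC, seTrain), yTrain)
  list(models = models, labels = info$labels, ids = info$ids,
       trainIds = trainIds, ranks = ranks)
}

modelAucTable <- function(fit, se, split) {
  valIds <- intersect(split$validation, fit$ids)
  do.call(rbind, lapply(names(fit$models), function(nm) {
    m <- fit$models[[nm]]
    sTr <- predictScore(m, se[, fit$trainIds])
    sVa <- predictScore(m, se[, valIds])
    data.frame(model = nm, endpoint = m@endpoint, roi = m@roi,
               nFeatures = length(m@features),
               trainAuc = rocAuc(sTr, fit$labels[fit$trainIds]),
               validationAuc = rocAuc(sVa, fit$labels[valIds]),
               stringsAsFactors = FALSE)
  }))
}

delongFamily <- function(fit, se) {
  scores <- lapply(fit$models, predictScore, data = se[, fit$ids])
  y <- fit$labels[fit$ids]
  nm <- names(fit$models)
  pairs <- utils::combn(length(nm), 2)
  tab <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    dl <- delongTest(scores[[i]], scores[[j]], y)
    data.frame(modelA = nm[i], modelB = nm[j], aucA = dl$aucA,
               aucB = dl$aucB, z = dl$z, p = dl$p, stringsAsFactors = FALSE)
  }))
  tab$pHolm <- holmAdjust(tab$p)
  tab
}

#' Run the full synthetic-cohort radiomics pipeline
#'
#' Generates a phantom cohort, extracts the 8 RFGs (4 phases x 2 ROIs),
#' splits 3:1 into training and validation (stratified by phenotype), fits
#' the 12 radiomic models (2 endpoints x [RFG1..4, SC, FC]), derives
#' Youden cutoffs on training scores, calls the three-class phenotype on
#' the validation cohort through the two-stage cascade, and reports AUCs,
#' the confusion matrix with accuracy and macro-F1, Holm-adjusted DeLong
#' model comparisons, and the score-CD8 density correlations.
#'
#' @param spec a [cohortSpec()].
#' @param seed master seed (cohort generation, split, CV folds).
#' @param topK univariate selection size (default 50).
#' @param iccThreshold ICC stability threshold (default 0.8).
#' @param nLevels gray levels for discretization (default 32).
#' @param rois ROIs to model; restrict to `"whole"` to fit only the
#'   inflamed-vs-noninflamed family (the three-class caller then needs both
#'   and is skipped).
#' @return A list of class `"radphenReport"`.
#' @export
runPipeline <- function(spec = cohortSpec(), seed = 20221219, topK = 50,
                        iccThreshold = 0.8, nLevels = 32,
                        rois = c("whole", "peri")) {
  cohort <- generateCohort(spec, seed)
  se <- extractCohortFeatures(cohort, nLevels = nLevels, rimMm = spec$rimMm,
                              rois = rois)
  split <- splitCohort(colnames(se), seed = seed,
                       stratify = SummarizedExperiment::colData(se)$phenotype)
  endpoints <- c(whole = "inflamed_vs_noninflamed",
                 peri = "desert_vs_excluded")[rois]
  fits <- lapply(endpoints, function(ep)
    fitEndpointModels(se, split, ep, topK = topK,
                      iccThreshold = iccThreshold, seed = seed))
  names(fits) <- rois
  aucTable <- do.call(rbind, lapply(rois, function(r)
    cbind(family = r, modelAucTable(fits[[r]], se, split))))
  delong <- lapply(fits, delongFamily, se = se)

  phen <- SummarizedExperiment::colData(se)$phenotype
  evaluation <- NULL
  calls <- NULL
  if (all(c("whole", "peri") %in% rois)) {
    valIds <- split$validation
    wholeScore <- predictScore(fits$whole$models$FC, se[, valIds])
    periScore <- predictScore(fits$peri$models$FC, se[, valIds])
    calls <- callPhenotype(wholeScore, periScore,
                           fits$whole$models$FC@cutoff,
                           fits$peri$models$FC@cutoff)
    names(calls) <- valIds
    evaluation <- evaluateCalls(calls, phen[match(valIds, colnames(se))])
  }

  correlations <- list()
  wholeAll <- predictScore(fits$whole$models$FC, se)
  correlations$wholeFC_cd8central <-
    pearsonCor(wholeAll, SummarizedExperiment::colData(se)$cd8_central)
  if ("peri" %in% rois) {
    periAll <- predictScore(fits$peri$models$FC, se)
    correlations$periFC_cd8peripheral <-
      pearsonCor(periAll, SummarizedExperiment::colData(se)$cd8_peripheral)
  }

  structure(list(seed = seed, spec = spec, split = split, features = se,
                 fits = fits, aucTable = aucTable, delong = delong,
                 calls = calls, evaluation = evaluation,
                 correlations = correlations),
            class = "radphenReport")
}

#' @export
print.radphenReport <- function(x, ...) {
  cat(sprintf("radphen pipeline report (seed %d): %d patients, %d/%d split\n",
              x$seed, ncol(x$features), length(x$split$training),
              length(x$split$validation)))
  print(x$aucTable[, c("family", "model", "nFeatures", "trainAuc",
                       "validationAuc")], row.names = FALSE, digits = 3)
  if (!is.null(x$evaluation)) {
    cat(sprintf("validation accuracy %.3f, macro-F1 %.3f\n",
                x$evaluation$accuracy, x$evaluation$macroF1))
    print(x$evaluation$confusion)
  }
  r <- x$correlations$wholeFC_cd8central
  cat(sprintf("RM-whole_FC score vs central CD8 density: r = %.3f, p = %.3g\n",
              r$r, r$p))
  invisible(x)
}

#' Score an external cohort with fitted models
#'
#' Applies fitted radiomic models to a new feature table and, when a
#' grouping (e.g. pathologic complete response) is supplied, compares the
#' scores between groups.
#'
#' @param models named list of [RadiomicModel-class] objects.
#' @param data a `SummarizedExperiment` of RFG assays or a patients x
#'   features matrix containing every model feature (missing features are
#'   reported by name).
#' @param grouping optional grouping vector aligned with the patients.
#' @return A list with `scores` (data.frame, one column per model) and,
#'   when a grouping is given, `tests` (per-model [groupCompare()] result).
#' @export
applyToExternalCohort <- function(models, data, grouping = NULL) {
  scores <- as.data.frame(lapply(models, predictScore, data = data))
  rownames(scores) <- if (is(data, "SummarizedExperiment")) colnames(data)
                      else rownames(data)
  out <- list(scores = scores)
  if (!is.null(grouping)) {
    if (length(grouping) != nrow(scores))
      stop("grouping length must match the number of patients")
    out$tests <- lapply(scores, function(s) groupCompare(s, grouping))
  }
  out
}
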