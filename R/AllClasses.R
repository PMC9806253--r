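#' VolumeWithMask: a 3D intensity volume with voxel spacing and a binary ROI
#'
#' The unit of image computation: a 3D array of intensities (arbitrary
#' units), the physical voxel spacing in mm, and a binary region-of-interest
#' mask of the same shape.
#'
#' @slot intensities 3D numeric array.
#' @slot spacing numeric(3), voxel spacing (dx, dy, dz) in mm, all > 0.
#' @slot mask 3D logical array, same shape as `intensities`.
#'
#' @export
setClass("VolumeWithMask",
  representation(intensities = "array", spacing = "numeric", mask = "array"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@intensities)) != 3L)
      msg <- c(msg, "intensities must be a 3D array")
    if (!identical(dim(object@intensities), dim(object@mask)))
      msg <- c(msg, "mask shape must equal intensity shape")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be three positive finite values (mm)")
    if (!is.logical(object@mask))
      msg <- c(msg, "mask must be a logical array")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a VolumeWithMask
#'
#' @param intensities 3D numeric array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param mask 3D array coercible to logical (integer label dialect: values
#'   > 0 are foreground); defaults to an all-foreground mask.
#' @return A [VolumeWithMask-class] object.
#' @examples
#' v <- VolumeWithMask(array(rnorm(8^3), c(8, 8, 8)), spacing = c(1, 1, 1))
#' @export
VolumeWithMask <- function(intensities, spacing = c(1, 1, 1), mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim(intensities))
  if (!is.logical(mask)) {
    m <- array(as.numeric(mask) > 0, dim(mask))
    mask <- m
  }
  storage.mode(intensities) <- "double"
  new("VolumeWithMask", intensities = intensities,
      spacing = as.numeric(spacing), mask = mask)
}

#' DiscretizedVolume: gray-level quantized ROI
#'
#' Integer gray levels in 1..G inside the mask, 0 outside, produced by
#' fixed-bin-count quantization of the in-mask intensity range.
#'
#' @slot levels 3D integer array (0 outside the ROI).
#' @slot nLevels integer, the number of gray levels G.
#' @slot spacing numeric(3), carried through from the source volume (mm).
#'
#' @export
setClass("DiscretizedVolume",
  representation(levels = "array", nLevels = "integer", spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@levels)) != 3L)
      msg <- c(msg, "levels must be a 3D array")
    if (object@nLevels < 2L) msg <- c(msg, "nLevels must be >= 2")
    inmask <- object@levels[object@levels > 0L]
    if (length(inmask) && (min(inmask) < 1L || max(inmask) > object@nLevels))
      msg <- c(msg, "in-mask levels must lie in [1, nLevels]")
    if (length(msg)) msg else TRUE
  }
)

#' RadiomicModel: a LASSO-derived radiomic scoring model
#'
#' Stores everything needed to reproduce the radiomic score on new data:
#' selected features (tagged with the RFG assay they come from), their
#' penalized-regression coefficients, the intercept, the regularization
#' strength chosen at minimum cross-validation error, and the training-set
#' standardization parameters. Score- and feature-combined models additionally
#' keep their nested per-phase models.
#'
#' @slot endpoint "inflamed_vs_noninflamed" or "desert_vs_excluded".
#' @slot roi "whole" or "peri".
#' @slot source which inputs the model was fit on (e.g. "RFG1", "SC", "FC").
#' @slot features character, selected feature names ("assay:feature" for
#'   feature-level inputs, "score:<model>" for score-level inputs).
#' @slot coefficients named numeric, nonzero coefficients on standardized
#'   features.
#' @slot intercept numeric(1).
#' @slot lambda numeric(1), penalty at minimum mean CV deviance.
#' @slot center,scale named numeric, training means / sds of the inputs.
#' @slot cutoff numeric(1), Youden-optimal score threshold (NA until set).
#' @slot submodels list of nested [RadiomicModel-class] objects (SC models).
#'
#' @export
setClass("RadiomicModel",
  representation(endpoint = "character", roi = "character", source = "character",
                 features = "character", coefficients = "numeric",
                 intercept = "numeric", lambda = "numeric",
                 center = "numeric", scale = "numeric",
                 cutoff = "numeric", submodels = "list"),
  prototype(cutoff = NA_real_, submodels = list()),
  validity = function(object) {
    msg <- character()
    if (length(object@features) < 1L)
      msg <- c(msg, "a fitted model must select at least one feature")
    if (any(object@coefficients == 0))
      msg <- c(msg, "all stored coefficients must be nonzero")
    if (!identical(sort(names(object@coefficients)), sort(object@features)))
      msg <- c(msg, "coefficient names must match the selected features")
    if (length(object@lambda) != 1L || object@lambda <= 0)
      msg <- c(msg, "lambda must be a single positive value")
    if (length(msg)) msg else TRUE
  }
)

#' SyntheticPatient: one generated phantom patient
#'
#' @slot id character patient identifier.
#' @slot phenotype "desert", "excluded" or "inflamed".
#' @slot images named list of five 3D arrays (pre, dce1..dce4) sharing one
#'   grid; the phases share a single tumor mask.
#' @slot mask 3D logical array (primary segmentation).
#' @slot secondMask second-rater segmentation (3D logical array), or an
#'   empty list entry when the patient is not in the re-segmented subset.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot cd8 named numeric(2): central and peripheral stromal CD8+ density
#'   (cells/mm^2), generated covariates.
#'
#' @export
setClass("SyntheticPatient",
  representation(id = "character", phenotype = "character", images = "list",
                 mask = "array", secondMask = "ANY", spacing = "numeric",
                 cd8 = "numeric"))

#' SyntheticCohort: a generated phantom DCE-MRI cohort
#'
#' @slot patients list of [SyntheticPatient-class] objects.
#' @slot spec the generator settings (as returned by [cohortSpec()]).
#' @slot seed integer seed the cohort was generated from.
#'
#' @export
setClass("SyntheticCohort",
  representation(patients = "list", spec = "list", seed = "integer"))

# ---- show methods ---------------------------------------------------------

setMethod("show", "VolumeWithMask", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("VolumeWithMask %dx%dx%d, spacing %s mm, %d/%d foreground voxels\n",
              d[1], d[2], d[3],
              paste(format(object@spacing, trim = TRUE), collapse = "x"),
              sum(object@mask), length(object@mask)))
})

setMethod("show", "DiscretizedVolume", function(object) {
  d <- dim(object@levels)
  cat(sprintf("DiscretizedVolume %dx%dx%d, G = %d, %d in-mask voxels\n",
              d[1], d[2], d[3], object@nLevels, sum(object@levels > 0L)))
})

setMethod("show", "RadiomicModel", function(object) {
  cat(sprintf("RadiomicModel [%s] %s / %s\n", object@source, object@endpoint,
              object@roi))
  cat(sprintf("  %d selected feature(s), lambda = %.4g, cutoff = %s\n",
              length(object@features), object@lambda,
              ifelse(is.na(object@cutoff), "unset",
                     format(object@cutoff, digits = 4))))
  if (length(object@submodels))
    cat(sprintf("  nests %d submodel(s)\n", length(object@submodels)))
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(factor(vapply(object@patients, slot, "", "phenotype"),
                      levels = c("desert", "excluded", "inflamed")))
  cat(sprintf("SyntheticCohort of %d patients (desert %d / excluded %d / inflamed %d), seed %d\n",
              length(object@patients), tab[1], tab[2], tab[3], object@seed))
})

# ---- accessors ------------------------------------------------------------

#' @describeIn VolumeWithMask-class the intensity array.
#' @param x,object a `VolumeWithMask`.
#' @export
intensities <- function(x) x@intensities

#' @describeIn VolumeWithMask-class the voxel spacing (mm).
#' @export
voxelSpacing <- function(x) x@spacing

#' @describeIn VolumeWithMask-class the logical ROI mask array.
#' @export
maskArray <- function(x) if (is(x, "DiscretizedVolume")) x@levels > 0L else x@mask

#' @describeIn DiscretizedVolume-class the integer level array (0 outside).
#' @param x a `DiscretizedVolume`.
#' @export
levelsArray <- function(x) x@levels

#' @describeIn DiscretizedVolume-class the number of gray levels G.
#' @export
nLevels <- function(x) x@nLevels

#' Patients of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return list of [SyntheticPatient-class] objects.
#' @export
cohortPatients <- function(x) x@patients

#' Phenotype labels of a synthetic cohort
#' @param x a [SyntheticCohort-class].
#' @return factor with levels desert, excluded, inflamed.
#' @export
cohortPhenotypes <- function(x) {
  factor(vapply(x@patients, slot, "", "phenotype"),
         levels = c("desert", "excluded", "inflamed"))
}

#' One DCE phase of a synthetic patient as a VolumeWithMask
#'
#' @param patient a [SyntheticPatient-class].
#' @param phase one of "pre", "dce1".."dce4".
#' @param useSecondMask use the second-rater segmentation instead of the
#'   primary one (only available for the re-segmented subset).
#' @return A [VolumeWithMask-class].
#' @export
phaseVolume <- function(patient, phase = "dce1", useSecondMask = FALSE) {
  img <- patient@images[[phase]]
  if (is.null(img)) stop("unknown phase: ", phase)
  msk <- if (useSecondMask) {
    if (!is.array(patient@secondMask))
      stop("patient ", patient@id, " has no second-rater segmentation")
    patient@secondMask
  } else patient@mask
  VolumeWithMask(img, patient@spacing, msk)
}
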