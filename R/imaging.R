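#' Read a volumetric image (NIfTI) with its companion ROI mask
#'
#' Reads a 3D image and, optionally, a companion mask file on the same grid.
#' Voxel spacing is taken from the NIfTI header (`pixdim`), which is treated
#' as authoritative. Mask files use the integer-label dialect: values > 0
#' are foreground.
#'
#' @param imagePath path to a `.nii`/`.nii.gz` image.
#' @param maskPath optional path to a companion mask file; when omitted an
#'   all-foreground mask is attached.
#' @return A [VolumeWithMask-class].
#' @export
readVolume <- function(imagePath, maskPath = NULL) {
  if (!file.exists(imagePath)) stop("image file not found: ", imagePath)
  img <- RNifti::readNifti(imagePath)
  if (length(dim(img)) != 3L) stop("expected a 3D image: ", imagePath)
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or invalid spacing metadata in ", imagePath)
  arr <- array(as.numeric(img), dim(img))
  mask <- NULL
  if (!is.null(maskPath)) {
    if (!file.exists(maskPath)) stop("mask file not found: ", maskPath)
    m <- RNifti::readNifti(maskPath)
    if (!identical(dim(m)[seq_len(3)], dim(arr)))
      stop("image/mask shape mismatch: ", paste(dim(arr), collapse = "x"),
           " vs ", paste(dim(m), collapse = "x"))
    mask <- array(as.numeric(m) > 0, dim(arr))
  }
  VolumeWithMask(arr, spacing, mask)
}

#' Write a VolumeWithMask to NIfTI files
#'
#' @param v a [VolumeWithMask-class].
#' @param imagePath output image path (`.nii`/`.nii.gz`).
#' @param maskPath optional output path for the mask (written as 0/1 labels).
#' @return `imagePath`, invisibly.
#' @export
writeVolume <- function(v, imagePath, maskPath = NULL) {
  img <- RNifti::asNifti(v@intensities)
  RNifti::pixdim(img) <- v@spacing
  RNifti::writeNifti(img, imagePath)
  if (!is.null(maskPath)) {
    m <- RNifti::asNifti(array(as.integer(v@mask), dim(v@mask)))
    RNifti::pixdim(m) <- v@spacing
    RNifti::writeNifti(m, maskPath)
  }
  invisible(imagePath)
}

#' Voxelwise subtraction image (post-contrast minus pre-contrast)
#'
#' The delineation image of the pipeline: the pre-contrast volume subtracted
#' from a post-contrast volume voxel by voxel. The ROI mask of `post` is
#' carried through unchanged.
#'
#' @param post,pre [VolumeWithMask-class] objects on the same grid.
#' @return A [VolumeWithMask-class] holding `post - pre`.
#' @export
subtractionImage <- function(post, pre) {
  if (!identical(dim(post@intensities), dim(pre@intensities)))
    stop("shape mismatch between post- and pre-contrast volumes")
  if (!isTRUE(all.equal(post@spacing, pre@spacing)))
    stop("spacing mismatch between post- and pre-contrast volumes")
  VolumeWithMask(post@intensities - pre@intensities, post@spacing, post@mask)
}

#' Resample a volume to isotropic voxels
#'
#' Linear interpolation for intensities, nearest neighbor for the mask.
#' Voxel centers sit at `index * spacing` with aligned origins; the output
#' grid covers the same physical extent.
#'
#' @param v a [VolumeWithMask-class].
#' @param targetMm target isotropic spacing in mm (> 0).
#' @return A [VolumeWithMask-class] with spacing `c(t, t, t)`.
#' @export
resampleIsotropic <- function(v, targetMm = 1) {
  stopifnot(targetMm > 0)
  d <- dim(v@intensities)
  outDim <- as.integer(floor((d - 1) * v@spacing / targetMm) + 1)
  outSp <- rep(targetMm, 3)
  arr <- cpp_resample_trilinear(v@intensities, v@spacing, outDim, outSp)
  m <- cpp_resample_nearest(array(as.integer(v@mask), d), v@spacing, outDim, outSp)
  if (sum(v@mask) > 0 && sum(m) == 0) {
    ext <- apply(which(v@mask, arr.ind = TRUE), 2, function(i) diff(range(i)))
    if (all((ext + 1) * v@spacing >= targetMm))
      stop("internal error: mask emptied by resampling although its physical ",
           "extent exceeds the target spacing")
  }
  VolumeWithMask(arr, outSp, array(m > 0L, outDim))
}

#' Distance (mm) of every voxel to the nearest out-of-mask voxel
#'
#' Exact Euclidean distance transform using the physical spacing, so the
#' result is in mm even on anisotropic voxels.
#'
#' @param mask 3D logical array.
#' @param spacing numeric(3) voxel spacing (mm).
#' @return 3D numeric array of distances (0 outside the mask).
#' @export
maskDepth <- function(mask, spacing) {
  bg <- array(!mask, dim(mask))
  d2 <- cpp_edt_sq(bg, as.numeric(spacing))
  d <- sqrt(d2)
  d[!mask] <- 0
  d
}

#' Extract the peripheral rim of a tumor ROI
#'
#' Replaces the mask by its inner rim: the in-mask voxels whose Euclidean
#' distance (in mm, using the voxel spacing) to the nearest out-of-mask
#' voxel is at most `rimMm`. Objects thinner than twice the rim everywhere
#' yield the whole mask back.
#'
#' @param v a [VolumeWithMask-class] with a non-empty mask.
#' @param rimMm rim thickness in mm (default 2, the inner 2-mm rim).
#' @return A [VolumeWithMask-class] whose mask is the rim.
#' @export
peripheralRim <- function(v, rimMm = 2) {
  stopifnot(rimMm > 0)
  if (!any(v@mask)) stop("empty input mask")
  depth <- maskDepth(v@mask, v@spacing)
  rim <- v@mask & (depth <= rimMm)
  VolumeWithMask(v@intensities, v@spacing, rim)
}

#' Discretize in-mask intensities to G gray levels
#'
#' Fixed-bin-count quantization over the in-mask intensity range:
#' `level = min(G, floor(G * (x - min) / (max - min)) + 1)`. A constant
#' region maps entirely to level 1. Discretized levels are invariant to
#' affine rescaling of the intensities, which makes downstream texture
#' features scale-free.
#'
#' @param v a [VolumeWithMask-class] with a non-empty mask.
#' @param nLevels number of gray levels G (>= 2, default 32).
#' @return A [DiscretizedVolume-class].
#' @export
discretizeVolume <- function(v, nLevels = 32) {
  nLevels <- as.integer(nLevels)
  stopifnot(nLevels >= 2L)
  if (!any(v@mask)) stop("empty input mask")
  x <- v@intensities[v@mask]
  lev <- array(0L, dim(v@intensities))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    lev[v@mask] <- 1L
  } else {
    lev[v@mask] <- pmin(nLevels,
                        as.integer(floor(nLevels * (x - rng[1]) / (rng[2] - rng[1]))) + 1L)
  }
  new("DiscretizedVolume", levels = lev, nLevels = nLevels,
      spacing = v@spacing)
}
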