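# The 13 unique 3D directions (distance-1 neighbors up to sign).
DIRECTIONS_3D <- matrix(c(
  1, 0, 0,
  0, 1, 0,
  0, 0, 1,
  1, 1, 0,
  1, -1, 0,
  1, 0, 1,
  1, 0, -1,
  0, 1, 1,
  0, 1, -1,
  1, 1, 1,
  1, 1, -1,
  1, -1, 1,
  1, -1, -1), ncol = 3, byrow = TRUE)

NGTDM_EPS <- 1e-6

#' First-order intensity statistics (14 features)
#'
#' Computed over the in-mask raw intensities, except `entropy` (base-2, over
#' the discretized level histogram) and `uniformity` (sum of squared level
#' probabilities). Variance is the population variance; skewness is the
#' standardized third moment and kurtosis the excess (Fisher) fourth moment,
#' both defined as 0 for a constant region.
#'
#' @param d a [DiscretizedVolume-class] of the same ROI.
#' @param v the [VolumeWithMask-class] the discretization came from.
#' @return Named numeric vector of 14 features (prefix `fo_`).
#' @export
firstOrderFeatures <- function(d, v) {
  x <- v@intensities[v@mask]
  if (!length(x)) stop("empty mask")
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  sk <- if (m2 > 0) mean((x - mu)^3) / m2^1.5 else 0
  ku <- if (m2 > 0) mean((x - mu)^4) / m2^2 - 3 else 0
  lev <- d@levels[d@levels > 0L]
  p <- tabulate(lev, nbins = d@nLevels) / length(lev)
  pp <- p[p > 0]
  c(fo_mean = mu,
    fo_median = median(x),
    fo_min = min(x),
    fo_max = max(x),
    fo_range = diff(range(x)),
    fo_variance = m2,
    fo_skewness = sk,
    fo_kurtosis = ku,
    fo_energy = sum(x^2),
    fo_entropy = -sum(pp * log2(pp)),
    fo_rms = sqrt(mean(x^2)),
    fo_mad = mean(abs(x - mu)),
    fo_uniformity = sum(p^2),
    fo_iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)))
}

#' Gray-level co-occurrence matrix
#'
#' Co-occurrences of in-mask voxel pairs accumulated over the supplied
#' directions at the given distance, symmetrized and normalized to sum 1.
#'
#' @param d a [DiscretizedVolume-class].
#' @param distance voxel offset distance (default 1).
#' @param directions integer matrix of direction vectors (rows); defaults to
#'   the 13 unique 3D directions.
#' @return A G x G probability matrix.
#' @export
glcmMatrix <- function(d, distance = 1, directions = DIRECTIONS_3D) {
  directions <- matrix(as.integer(directions), ncol = 3)
  C <- cpp_glcm_counts(d@levels, d@nLevels, as.integer(distance), directions)
  tot <- sum(C)
  if (tot == 0)
    stop("degenerate ROI: no in-mask voxel pairs under the given directions")
  C / tot
}

#' GLCM texture features (13)
#'
#' Haralick-type features of a normalized, symmetric co-occurrence matrix:
#' contrast, dissimilarity, homogeneity (inverse difference moment), energy
#' (angular second moment), entropy (bits), correlation, cluster shade,
#' cluster prominence, maximum probability, sum average, sum entropy,
#' difference entropy, and inverse difference normalized. Correlation of a
#' zero-variance (single-level) matrix is defined as 1.
#'
#' @param P a normalized symmetric G x G co-occurrence matrix.
#' @return Named numeric vector of 13 features (prefix `glcm_`).
#' @export
glcmFeatures <- function(P) {
  if (abs(sum(P) - 1) > 1e-8) stop("co-occurrence matrix must be normalized")
  G <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mux <- sum(seq_len(G) * px)
  sigx <- sqrt(sum((seq_len(G) - mux)^2 * px))
  pos <- P > 0
  ent <- -sum(P[pos] * log2(P[pos]))
  corr <- if (sigx > 0) (sum(i * j * P) - mux^2) / sigx^2 else 1
  # diagonal-band distributions
  ks <- 2:(2 * G)
  pxy_sum <- vapply(ks, function(k) sum(P[(i + j) == k]), 0)
  kd <- 0:(G - 1)
  pxy_dif <- vapply(kd, function(k) sum(P[abs(i - j) == k]), 0)
  se <- pxy_sum[pxy_sum > 0]
  de <- pxy_dif[pxy_dif > 0]
  c(glcm_contrast = sum((i - j)^2 * P),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_energy = sum(P^2),
    glcm_entropy = ent,
    glcm_correlation = corr,
    glcm_cluster_shade = sum((i + j - 2 * mux)^3 * P),
    glcm_cluster_prominence = sum((i + j - 2 * mux)^4 * P),
    glcm_max_probability = max(P),
    glcm_sum_average = sum(ks * pxy_sum),
    glcm_sum_entropy = -sum(se * log2(se)),
    glcm_difference_entropy = -sum(de * log2(de)),
    glcm_idn = sum(P / (1 + abs(i - j) / G)))
}

#' Gray-level run-length matrix for one direction
#'
#' Counts maximal in-mask runs of constant level along the direction; rows
#' are gray levels, columns run lengths.
#'
#' @param d a [DiscretizedVolume-class].
#' @param direction integer vector of length 3.
#' @return A G x Rmax count matrix.
#' @export
glrlmMatrix <- function(d, direction) {
  cpp_glrlm_counts(d@levels, d@nLevels, as.integer(direction))
}

glrlmFeaturesFromMatrix <- function(R, nVoxels) {
  Nr <- sum(R)
  g <- seq_len(nrow(R)); r <- seq_len(ncol(R))
  gi <- matrix(g, nrow(R), ncol(R))
  rj <- matrix(r, nrow(R), ncol(R), byrow = TRUE)
  p <- R / Nr
  mug <- sum(gi * p); mur <- sum(rj * p)
  pp <- p[p > 0]
  c(glrlm_sre = sum(R / rj^2) / Nr,
    glrlm_lre = sum(R * rj^2) / Nr,
    glrlm_gln = sum(rowSums(R)^2) / Nr,
    glrlm_glnn = sum(rowSums(R)^2) / Nr^2,
    glrlm_rln = sum(colSums(R)^2) / Nr,
    glrlm_rlnn = sum(colSums(R)^2) / Nr^2,
    glrlm_rp = Nr / nVoxels,
    glrlm_glv = sum(p * (gi - mug)^2),
    glrlm_rv = sum(p * (rj - mur)^2),
    glrlm_re = -sum(pp * log2(pp)),
    glrlm_lglre = sum(R / gi^2) / Nr,
    glrlm_hglre = sum(R * gi^2) / Nr,
    glrlm_srlgle = sum(R / (gi^2 * rj^2)) / Nr,
    glrlm_srhgle = sum(R * gi^2 / rj^2) / Nr,
    glrlm_lrlgle = sum(R * rj^2 / gi^2) / Nr,
    glrlm_lrhgle = sum(R * gi^2 * rj^2) / Nr)
}

#' GLRLM texture features (16)
#'
#' A run-length matrix is built per direction (the 13 unique 3D directions)
#' over maximal in-mask runs, features computed per matrix and averaged over
#' directions.
#'
#' @param d a [DiscretizedVolume-class] with a non-empty mask.
#' @return Named numeric vector of 16 features (prefix `glrlm_`).
#' @export
glrlmFeatures <- function(d) {
  nVox <- sum(d@levels > 0L)
  if (nVox == 0) stop("empty mask")
  feats <- vapply(seq_len(nrow(DIRECTIONS_3D)), function(k) {
    glrlmFeaturesFromMatrix(glrlmMatrix(d, DIRECTIONS_3D[k, ]), nVox)
  }, numeric(16))
  rowMeans(feats)
}

#' Gray-level size-zone matrix
#'
#' Zones are 26-connected in-mask components of equal gray level; rows are
#' gray levels, columns zone sizes.
#'
#' @param d a [DiscretizedVolume-class].
#' @return A G x Zmax count matrix.
#' @export
glszmMatrix <- function(d) {
  if (!any(d@levels > 0L)) stop("empty mask")
  cpp_glszm_counts(d@levels, d@nLevels)
}

#' GLSZM texture features (16)
#'
#' Size-zone analogues of the run-length features, computed from the single
#' (direction-free) size-zone matrix.
#'
#' @param d a [DiscretizedVolume-class] with a non-empty mask.
#' @return Named numeric vector of 16 features (prefix `glszm_`).
#' @export
glszmFeatures <- function(d) {
  nVox <- sum(d@levels > 0L)
  Z <- glszmMatrix(d)
  Nz <- sum(Z)
  g <- seq_len(nrow(Z)); s <- seq_len(ncol(Z))
  gi <- matrix(g, nrow(Z), ncol(Z))
  sj <- matrix(s, nrow(Z), ncol(Z), byrow = TRUE)
  p <- Z / Nz
  mug <- sum(gi * p); mus <- sum(sj * p)
  pp <- p[p > 0]
  c(glszm_sae = sum(Z / sj^2) / Nz,
    glszm_lae = sum(Z * sj^2) / Nz,
    glszm_gln = sum(rowSums(Z)^2) / Nz,
    glszm_glnn = sum(rowSums(Z)^2) / Nz^2,
    glszm_szn = sum(colSums(Z)^2) / Nz,
    glszm_sznn = sum(colSums(Z)^2) / Nz^2,
    glszm_zp = Nz / nVox,
    glszm_glv = sum(p * (gi - mug)^2),
    glszm_zv = sum(p * (sj - mus)^2),
    glszm_ze = -sum(pp * log2(pp)),
    glszm_lglze = sum(Z / gi^2) / Nz,
    glszm_hglze = sum(Z * gi^2) / Nz,
    glszm_salgle = sum(Z / (gi^2 * sj^2)) / Nz,
    glszm_sahgle = sum(Z * gi^2 / sj^2) / Nz,
    glszm_lalgle = sum(Z * sj^2 / gi^2) / Nz,
    glszm_lahgle = sum(Z * gi^2 * sj^2) / Nz)
}

#' Neighborhood gray-tone difference table
#'
#' For each gray level i: the number of in-mask voxels of level i that have
#' at least one in-mask 26-neighbor (`n_i`), their occupancy probability
#' `p_i`, and the summed absolute difference `s_i` between i and the mean
#' level of each voxel's in-mask neighborhood.
#'
#' @param d a [DiscretizedVolume-class].
#' @return A data.frame with columns `level`, `n`, `p`, `s`.
#' @export
ngtdmTable <- function(d) {
  if (!any(d@levels > 0L)) stop("empty mask")
  M <- cpp_ngtdm_table(d@levels, d@nLevels)
  nv <- sum(M[, 1])
  data.frame(level = seq_len(d@nLevels), n = M[, 1],
             p = if (nv > 0) M[, 1] / nv else M[, 1], s = M[, 2])
}

#' NGTDM texture features (5)
#'
#' Amadasun-King coarseness, contrast, busyness, complexity and strength,
#' with an epsilon guard (1e-6) on zero denominators: a perfectly flat
#' region has all `s_i = 0`, giving the documented capped coarseness 1e6 and
#' zero contrast/busyness/complexity/strength.
#'
#' @param d a [DiscretizedVolume-class] with a non-empty mask.
#' @return Named numeric vector of 5 features (prefix `ngtdm_`).
#' @export
ngtdmFeatures <- function(d) {
  tb <- ngtdmTable(d)
  act <- tb$p > 0
  i <- tb$level[act]; p <- tb$p[act]; s <- tb$s[act]
  Nv <- sum(tb$n)
  Ngp <- length(i)
  ps <- sum(p * s)
  coarseness <- if (ps > NGTDM_EPS) 1 / ps else 1 / NGTDM_EPS
  II <- outer(i, i, "-")
  PP <- outer(p, p)
  contrast <- if (Ngp > 1)
    (sum(PP * II^2) / (Ngp * (Ngp - 1))) * (sum(s) / Nv) else 0
  busyDen <- sum(abs(outer(i * p, i * p, "-")))
  busyness <- if (busyDen > NGTDM_EPS) ps / busyDen else 0
  complexity <- if (Ngp > 1) {
    sumPS <- outer(p * s, p * s, "+")
    sum(abs(II) * sumPS / outer(p, p, "+")) / Nv
  } else 0
  strength <- if (sum(s) > NGTDM_EPS)
    sum(outer(p, p, "+") * II^2) / sum(s) else 0
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}

TEXTURE_FEATURE_NAMES <- c(
  "fo_mean", "fo_median", "fo_min", "fo_max", "fo_range", "fo_variance",
  "fo_skewness", "fo_kurtosis", "fo_energy", "fo_entropy", "fo_rms",
  "fo_mad", "fo_uniformity", "fo_iqr",
  "glcm_contrast", "glcm_dissimilarity", "glcm_homogeneity", "glcm_energy",
  "glcm_entropy", "glcm_correlation", "glcm_cluster_shade",
  "glcm_cluster_prominence", "glcm_max_probability", "glcm_sum_average",
  "glcm_sum_entropy", "glcm_difference_entropy", "glcm_idn",
  "glrlm_sre", "glrlm_lre", "glrlm_gln", "glrlm_glnn", "glrlm_rln",
  "glrlm_rlnn", "glrlm_rp", "glrlm_glv", "glrlm_rv", "glrlm_re",
  "glrlm_lglre", "glrlm_hglre", "glrlm_srlgle", "glrlm_srhgle",
  "glrlm_lrlgle", "glrlm_lrhgle",
  "glszm_sae", "glszm_lae", "glszm_gln", "glszm_glnn", "glszm_szn",
  "glszm_sznn", "glszm_zp", "glszm_glv", "glszm_zv", "glszm_ze",
  "glszm_lglze", "glszm_hglze", "glszm_salgle", "glszm_sahgle",
  "glszm_lalgle", "glszm_lahgle",
  "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness",
  "ngtdm_complexity", "ngtdm_strength")

#' The 64 texture features of one image/ROI
#'
#' 14 first-order + 13 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM features of a
#' masked volume, computed on its fixed-bin-count discretization. Runs as a
#' single fused pass; the modular builders ([glcmMatrix()],
#' [glcmFeatures()], [glrlmFeatures()], [glszmFeatures()],
#' [ngtdmFeatures()], [firstOrderFeatures()]) define the reference values
#' it reproduces.
#'
#' @param v a [VolumeWithMask-class] with a non-empty mask.
#' @param nLevels gray levels for discretization (default 32).
#' @return Named numeric vector of 64 features.
#' @export
textureFeatures <- function(v, nLevels = 32) {
  out <- cpp_texture_features(v@intensities, v@mask, as.integer(nLevels))
  names(out) <- TEXTURE_FEATURE_NAMES
  out
}

# modular composition of the same 64 features; the fused kernel is tested
# against this path
textureFeaturesReference <- function(v, nLevels = 32) {
  d <- discretizeVolume(v, nLevels)
  P <- glcmMatrix(d)
  c(firstOrderFeatures(d, v), glcmFeatures(P), glrlmFeatures(d),
    glszmFeatures(d), ngtdmFeatures(d))
}

# crop a volume to the mask bounding box plus `pad` voxels; texture features
# only see in-mask voxels, so this is exact and keeps the wavelet transform
# and matrix scans small
cropToMask <- function(v, pad = 4L) {
  idx <- which(v@mask, arr.ind = TRUE)
  d <- dim(v@mask)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  VolumeWithMask(v@intensities[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
                 v@spacing,
                 v@mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE])
}

#' Extract one radiomic feature group (RFG, 833 features)
#'
#' The full feature vector of one ROI on one DCE phase: the ROI volume in
#' mm^3, the 64 texture features of the original image, and the 64 texture
#' features of each of the 12 wavelet band-weighted images (768 wavelet
#' features), in deterministic order with systematic names. Wavelet-filtered
#' images are re-discretized independently because their intensity range
#' differs from the original.
#'
#' @param v a [VolumeWithMask-class] holding the whole-tumor ROI.
#' @param roi `"whole"` for the whole tumor or `"peri"` for the inner rim.
#' @param nLevels gray levels for discretization (default 32).
#' @param rimMm rim thickness in mm for the `"peri"` ROI (default 2).
#' @return Named numeric vector of length 833.
#' @export
extractRFG <- function(v, roi = c("whole", "peri"), nLevels = 32, rimMm = 2) {
  roi <- match.arg(roi)
  out <- extractPhaseRFGs(v, roi, nLevels, rimMm)[[roi]]
  stopifnot(length(out) == 833L, !anyDuplicated(names(out)))
  out
}
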