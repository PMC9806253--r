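# Orthogonal filter taps (published Daubechies-2, Coiflet-1 and Symlet-4
# coefficients); dec_* analyse, rec_* synthesize.
WAVELET_FILTERS <- list(
  db2 = list(
    dec_lo = c(-0.12940952255126037, 0.22414386804201340,
               0.83651630373780790, 0.48296291314453416),
    dec_hi = c(-0.48296291314453416, 0.83651630373780790,
               -0.22414386804201340, -0.12940952255126037),
    rec_lo = c(0.48296291314453416, 0.83651630373780790,
               0.22414386804201340, -0.12940952255126037),
    rec_hi = c(-0.12940952255126037, -0.22414386804201340,
               0.83651630373780790, -0.48296291314453416)),
  coif1 = list(
    dec_lo = c(-0.015655728135791993, -0.072732619512526450,
               0.384864846864857800, 0.852572020211600400,
               0.337897662457481800, -0.072732619512526450),
    dec_hi = c(0.072732619512526450, 0.337897662457481800,
               -0.852572020211600400, 0.384864846864857800,
               0.072732619512526450, -0.015655728135791993),
    rec_lo = c(-0.072732619512526450, 0.337897662457481800,
               0.852572020211600400, 0.384864846864857800,
               -0.072732619512526450, -0.015655728135791993),
    rec_hi = c(-0.015655728135791993, 0.072732619512526450,
               0.384864846864857800, -0.852572020211600400,
               0.337897662457481800, 0.072732619512526450)),
  sym4 = list(
    dec_lo = c(-0.075765714789273330, -0.029635527645998510,
               0.497618667632015450, 0.803738751805916100,
               0.297857795605277360, -0.099219543576847220,
               -0.012603967262037833, 0.032223100604042700),
    dec_hi = c(-0.032223100604042700, -0.012603967262037833,
               0.099219543576847220, 0.297857795605277360,
               -0.803738751805916100, 0.497618667632015450,
               0.029635527645998510, -0.075765714789273330),
    rec_lo = c(0.032223100604042700, -0.012603967262037833,
               -0.099219543576847220, 0.297857795605277360,
               0.803738751805916100, 0.497618667632015450,
               -0.029635527645998510, -0.075765714789273330),
    rec_hi = c(-0.075765714789273330, 0.029635527645998510,
               0.497618667632015450, -0.803738751805916100,
               0.297857795605277360, 0.099219543576847220,
               -0.012603967262037833, -0.032223100604042700))
)

WAVELET_RATIOS <- c(1 / 2, 2 / 3, 3 / 2, 2)

ratioLabel <- function(ratio) {
  # stable short labels for feature names
  lab <- c("0.5", "0.67", "1.5", "2")[match(ratio, WAVELET_RATIOS)]
  ifelse(is.na(lab), format(ratio, digits = 3), lab)
}

#' The 12 admissible wavelet band-weighting specifications
#'
#' Three wavelet families (db2, coif1, sym4) crossed with four low-frequency
#' band weights (1/2, 2/3, 3/2, 2), in deterministic family-major order with
#' ratios ascending.
#'
#' @return A data.frame with columns `family`, `ratio` and `label` (12 rows).
#' @examples
#' waveletSpecs()
#' @export
waveletSpecs <- function() {
  fam <- names(WAVELET_FILTERS)
  out <- expand.grid(ratio = WAVELET_RATIOS, family = fam,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[, c("family", "ratio")]
  out$label <- paste0(out$family, "_r", ratioLabel(out$ratio))
  rownames(out) <- NULL
  out
}

#' Wavelet band-weighted filtering of a volume
#'
#' Single-level separable 3D discrete wavelet decomposition with symmetric
#' boundary extension; the all-low-pass (LLL) sub-band is multiplied by
#' `ratio` while the seven detail sub-bands keep weight 1, and the inverse
#' transform returns a volume of the original shape. A ratio below 1
#' suppresses the low-frequency content, a ratio above 1 amplifies it, and
#' ratio 1 reproduces the input exactly. The ROI mask is carried through
#' unchanged.
#'
#' @param v a [VolumeWithMask-class]; every axis must be at least as long as
#'   the filter support (4 for db2, 6 for coif1, 8 for sym4).
#' @param family one of `"db2"`, `"coif1"`, `"sym4"`.
#' @param ratio the weight applied to the approximation sub-band.
#' @return A [VolumeWithMask-class] with filtered intensities.
#' @export
waveletFilter <- function(v, family = c("db2", "coif1", "sym4"), ratio = 1) {
  family <- match.arg(family)
  f <- WAVELET_FILTERS[[family]]
  out <- cpp_wavelet_ratio(v@intensities, f$dec_lo, f$dec_hi,
                           f$rec_lo, f$rec_hi, ratio)
  VolumeWithMask(out, v@spacing, v@mask)
}

#' The 12-image wavelet filter bank
#'
#' Applies [waveletFilter()] for every admissible specification (see
#' [waveletSpecs()]), returning exactly 12 filtered volumes in deterministic
#' family-major order, each tagged with its specification label for feature
#' naming.
#'
#' @param v a [VolumeWithMask-class].
#' @details By linearity of the transform, the band-weighted output equals
#' `v + (ratio - 1) * A` where `A` is the reconstruction of the LLL sub-band
#' alone, so the bank shares one approximation per family across its four
#' ratios instead of running twelve full decompositions.
#'
#' @return A named list of 12 [VolumeWithMask-class] objects; names are the
#'   spec labels (e.g. `"db2_r0.5"`).
#' @export
filterBank <- function(v) {
  specs <- waveletSpecs()
  out <- vector("list", nrow(specs))
  names(out) <- specs$label
  for (fam in unique(specs$family)) {
    f <- WAVELET_FILTERS[[fam]]
    A <- cpp_wavelet_approx(v@intensities, f$dec_lo, f$rec_lo)
    for (i in which(specs$family == fam)) {
      out[[i]] <- VolumeWithMask(v@intensities + (specs$ratio[i] - 1) * A,
                                 v@spacing, v@mask)
    }
  }
  out
}
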