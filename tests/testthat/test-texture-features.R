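test_that("first-order statistics match hand values and order laws", {
  d <- c(2, 2, 1)
  v <- VolumeWithMask(array(c(1, 2, 3, 4), d), mask = array(TRUE, d))
  fo <- firstOrderFeatures(discretizeVolume(v, 4), v)
  expect_equal(fo[["fo_mean"]], 2.5)
  expect_equal(fo[["fo_variance"]], 1.25)
  expect_equal(fo[["fo_entropy"]], 2)            # 2 bits, uniform on 4 levels
  expect_equal(fo[["fo_median"]], 2.5)
  expect_equal(fo[["fo_range"]], 3)
  vc <- VolumeWithMask(array(5, c(3, 3, 2)))
  foc <- firstOrderFeatures(discretizeVolume(vc, 8), vc)
  expect_equal(foc[["fo_variance"]], 0)
  expect_equal(foc[["fo_entropy"]], 0)
  expect_equal(foc[["fo_uniformity"]], 1)
  expect_equal(foc[["fo_range"]], 0)
  expect_equal(foc[["fo_skewness"]], 0)
  for (s in 1:5) {
    w <- randomVolume(s)
    f <- firstOrderFeatures(discretizeVolume(w, 16), w)
    expect_lte(f[["fo_min"]], f[["fo_median"]])
    expect_lte(f[["fo_median"]], f[["fo_max"]])
    expect_gte(f[["fo_rms"]]^2, f[["fo_mean"]]^2)
  }
})

test_that("GLCM matrix matches hand enumeration and the brute-force oracle", {
  lev <- array(c(1L, 2L, 2L, 1L), c(2, 2, 1))
  d <- discFromLevels(lev, 2)
  dirs <- matrix(c(0, 1, 0, 1, 0, 0), ncol = 3, byrow = TRUE)
  P <- glcmMatrix(d, directions = dirs)
  expect_equal(P[1, 2], 0.5)
  expect_equal(P[2, 1], 0.5)
  expect_equal(sum(P), 1)
  expect_equal(glcmFeatures(P)[["glcm_contrast"]], 1.0)
  # constant region
  cl <- array(1L, c(3, 3, 3))
  Pc <- glcmMatrix(discFromLevels(cl, 4))
  expect_equal(Pc[1, 1], 1)
  fc <- glcmFeatures(Pc)
  expect_equal(fc[["glcm_contrast"]], 0)
  expect_equal(fc[["glcm_max_probability"]], 1)
  # brute-force oracle over random masked volumes
  for (s in 1:10) {
    lev <- randLevels(s, c(8, 8, 8), 5)
    if (sum(lev > 0) < 10) next
    d <- discFromLevels(lev, 5)
    C <- bfGlcmCounts(lev, 5, radphen:::DIRECTIONS_3D)
    expect_equal(glcmMatrix(d), C / sum(C))
  }
  expect_error(glcmMatrix(discFromLevels(array(c(1L, rep(0L, 26)), c(3, 3, 3)), 2)),
               "degenerate")
})

test_that("GLCM features match an independent literal-formula implementation", {
  # two-cell matrix hand values
  P <- matrix(0, 2, 2); P[1, 2] <- P[2, 1] <- 0.5
  f <- glcmFeatures(P)
  expect_equal(f[["glcm_energy"]], 0.5)
  expect_equal(f[["glcm_entropy"]], 1)
  expect_equal(f[["glcm_contrast"]], 1)
  # diagonal-uniform matrix
  Pd <- diag(4) / 4
  fd <- glcmFeatures(Pd)
  expect_equal(fd[["glcm_contrast"]], 0)
  expect_equal(fd[["glcm_dissimilarity"]], 0)
  expect_equal(fd[["glcm_homogeneity"]], 1)
  for (s in 1:10) {
    lev <- randLevels(100 + s, c(7, 7, 6), 6)
    if (sum(lev > 0) < 10) next
    P <- glcmMatrix(discFromLevels(lev, 6))
    expect_equal(glcmFeatures(P), glcmFeatureOracle(P), tolerance = 1e-12)
  }
})

test_that("GLCM feature invariance under order-preserving relabeling is per-feature", {
  # doubling the gap between levels changes contrast but not ASM/entropy
  levA <- randLevels(42, c(6, 6, 6), 3)
  levB <- levA
  levB[levA == 2L] <- 3L
  levB[levA == 3L] <- 5L
  fA <- glcmFeatures(glcmMatrix(discFromLevels(levA, 3)))
  fB <- glcmFeatures(glcmMatrix(discFromLevels(levB, 5)))
  expect_equal(fA[["glcm_energy"]], fB[["glcm_energy"]], tolerance = 1e-12)
  expect_equal(fA[["glcm_entropy"]], fB[["glcm_entropy"]], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(fA[["glcm_contrast"]], fB[["glcm_contrast"]])))
})

test_that("GLRLM runs match closed forms and the rle-based oracle", {
  # single constant line along the run direction
  N <- 7
  lev <- array(1L, c(1, N, 1))
  M <- glrlmMatrix(discFromLevels(lev, 2), c(0, 1, 0))
  f <- radphen:::glrlmFeaturesFromMatrix(M, N)
  expect_equal(f[["glrlm_sre"]], 1 / N^2)
  expect_equal(f[["glrlm_lre"]], N^2)
  expect_equal(f[["glrlm_rp"]], 1 / N)
  # alternating levels: all runs length 1
  lev2 <- array(rep(c(1L, 2L), length.out = 9), c(1, 9, 1))
  M2 <- glrlmMatrix(discFromLevels(lev2, 2), c(0, 1, 0))
  f2 <- radphen:::glrlmFeaturesFromMatrix(M2, 9)
  expect_equal(f2[["glrlm_sre"]], 1)
  expect_equal(f2[["glrlm_rp"]], 1)
  # oracle equivalence per direction on random volumes
  for (s in 1:8) {
    lev <- randLevels(200 + s, c(6, 6, 6), 4)
    if (sum(lev > 0) < 10) next
    d <- discFromLevels(lev, 4)
    for (r in c(1, 5, 10, 13)) {
      dir <- radphen:::DIRECTIONS_3D[r, ]
      A <- glrlmMatrix(d, dir)
      B <- bfGlrlmCounts(lev, 4, dir)
      mc <- max(ncol(A), ncol(B))
      pad <- function(M) cbind(M, matrix(0, nrow(M), mc - ncol(M)))
      expect_equal(pad(A), pad(B), ignore_attr = TRUE)
    }
  }
})

test_that("GLSZM zones match closed forms and the BFS oracle", {
  # one constant region -> a single zone of size V
  m <- array(FALSE, c(5, 5, 3)); m[2:4, 2:4, 1:2] <- TRUE
  lev <- array(0L, c(5, 5, 3)); lev[m] <- 1L
  V <- sum(m)
  f <- glszmFeatures(discFromLevels(lev, 2))
  expect_equal(f[["glszm_zp"]], 1 / V)
  expect_equal(f[["glszm_sae"]], 1 / V^2)
  expect_equal(f[["glszm_lae"]], V^2)
  # spaced isolated voxels: every zone size 1
  lev2 <- array(0L, c(5, 5, 1))
  lev2[1, 1, 1] <- 1L; lev2[1, 4, 1] <- 1L; lev2[4, 1, 1] <- 1L; lev2[4, 4, 1] <- 1L
  f2 <- glszmFeatures(discFromLevels(lev2, 2))
  expect_equal(f2[["glszm_sae"]], 1)
  for (s in 1:8) {
    lev <- randLevels(300 + s, c(6, 6, 6), 4)
    if (sum(lev > 0) < 10) next
    A <- glszmMatrix(discFromLevels(lev, 4))
    B <- bfGlszmCounts(lev, 4)
    mc <- max(ncol(A), ncol(B))
    pad <- function(M) cbind(M, matrix(0, nrow(M), mc - ncol(M)))
    expect_equal(pad(A), pad(B), ignore_attr = TRUE)
  }
})

test_that("NGTDM table matches hand enumeration and the neighborhood-loop oracle", {
  # 3x3x1, all level 1 except a level-2 center: hand-enumerable
  lev <- array(1L, c(3, 3, 1)); lev[2, 2, 1] <- 2L
  tb <- ngtdmTable(discFromLevels(lev, 2))
  expect_equal(tb$n, c(8, 1))
  expect_equal(tb$s, c(4 / 3 + 4 / 5, 1), tolerance = 1e-12)
  # constant region: capped coarseness, zero contrast
  fc <- ngtdmFeatures(discFromLevels(array(2L, c(4, 4, 4)), 3))
  expect_equal(fc[["ngtdm_coarseness"]], 1e6)
  expect_equal(fc[["ngtdm_contrast"]], 0)
  for (s in 1:8) {
    lev <- randLevels(400 + s, c(6, 6, 6), 4)
    if (sum(lev > 0) < 10) next
    tb <- ngtdmTable(discFromLevels(lev, 4))
    bf <- bfNgtdm(lev, 4)
    expect_equal(tb$n, bf$n)
    expect_equal(tb$s, bf$s, tolerance = 1e-10)
  }
})

test_that("the fused texture kernel reproduces the modular reference exactly", {
  for (s in 1:15) {
    v <- randomVolume(500 + s, dims = c(7, 8, 6))
    if (sum(maskArray(v)) < 12) next
    a <- textureFeatures(v, 8)
    b <- radphen:::textureFeaturesReference(v, 8)
    expect_equal(a, b, tolerance = 1e-12)
    expect_true(all(is.finite(a)))
  }
})

test_that("an RFG has 833 uniquely named finite features with the stated split", {
  m <- sphereMask(5)
  v <- VolumeWithMask(array(rnorm(prod(dim(m))), dim(m)), c(1, 1, 1), m)
  rfg <- extractRFG(v, "whole")
  expect_length(rfg, 833)
  expect_false(anyDuplicated(names(rfg)) > 0)
  expect_equal(sum(grepl("^wav_", names(rfg))), 768)
  expect_equal(sum(grepl("^orig_", names(rfg))), 64)
  expect_lt(abs(rfg[["volume_mm3"]] - 4 / 3 * pi * 125) / (4 / 3 * pi * 125),
            0.05)
  expect_true(all(is.finite(rfg)))
  expect_identical(rfg, extractRFG(v, "whole"))   # determinism
  peri <- extractRFG(v, "peri")
  expect_length(peri, 833)
  expect_lt(peri[["volume_mm3"]], rfg[["volume_mm3"]])
})
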