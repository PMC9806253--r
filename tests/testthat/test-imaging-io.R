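test_that("NIfTI round trip preserves shape, spacing and mask pairing", {
  dir <- withr::local_tempdir()
  img <- file.path(dir, "img.nii.gz"); msk <- file.path(dir, "msk.nii.gz")
  set.seed(1)
  v <- VolumeWithMask(array(rnorm(20 * 20 * 10), c(20, 20, 10)),
                      spacing = c(0.6, 0.6, 2.0),
                      mask = sphereMask(4, c(0.6, 0.6, 2.0), marginMm = 6)[1:20, 1:20, 1:10])
  writeVolume(v, img, msk)
  r <- readVolume(img, msk)
  expect_identical(dim(intensities(r)), dim(intensities(v)))
  expect_equal(voxelSpacing(r), c(0.6, 0.6, 2.0), tolerance = 1e-6)
  expect_equal(maskArray(r), maskArray(v))
  expect_equal(intensities(r), intensities(v), tolerance = 1e-6,
               ignore_attr = TRUE)

  bad <- file.path(dir, "bad.nii.gz")
  writeVolume(VolumeWithMask(array(0, c(20, 20, 9))), bad)
  expect_error(readVolume(img, bad), "mismatch")
  expect_error(readVolume(file.path(dir, "none.nii.gz")), "not found")
})

test_that("subtraction image is exact voxelwise difference with mask carry", {
  d <- c(6, 5, 4)
  mk <- array(TRUE, d)
  pre <- VolumeWithMask(array(2, d), mask = mk)
  post <- VolumeWithMask(array(5, d), mask = mk)
  expect_true(all(intensities(subtractionImage(post, pre)) == 3))
  expect_true(all(intensities(subtractionImage(post, post)) == 0))
  set.seed(2)
  A <- VolumeWithMask(array(rnorm(prod(d)), d), mask = mk)
  B <- VolumeWithMask(array(rnorm(prod(d)), d), mask = mk)
  # elementwise loop oracle
  ref <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    ref[i, j, k] <- intensities(A)[i, j, k] - intensities(B)[i, j, k]
  expect_equal(intensities(subtractionImage(A, B)), ref)
  # inverse of addition
  back <- intensities(subtractionImage(A, B)) + intensities(B)
  expect_equal(back, intensities(A), tolerance = 1e-12)
  expect_error(subtractionImage(A, VolumeWithMask(array(0, c(6, 5, 3)))),
               "mismatch")
})

test_that("isotropic resampling preserves constants, no-ops and volumes", {
  set.seed(3)
  v <- VolumeWithMask(array(rnorm(8 * 7 * 6), c(8, 7, 6)), c(1, 1, 1))
  expect_equal(intensities(resampleIsotropic(v, 1)), intensities(v))
  vc <- VolumeWithMask(array(4.2, c(8, 8, 8)), c(1, 1, 2))
  expect_true(all(abs(intensities(resampleIsotropic(vc, 1)) - 4.2) < 1e-12))
  # 10-mm sphere resampled 2 mm -> 1 mm: volume within 5% of analytic
  m <- sphereMask(10, c(2, 2, 2))
  sv <- VolumeWithMask(array(0, dim(m)), c(2, 2, 2), m)
  r <- resampleIsotropic(sv, 1)
  vol <- sum(maskArray(r)) * 1
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  # smooth phantom round trip changes in-mask mean by < 1%
  d <- c(12, 12, 12)
  ax <- seq(0, 1, length.out = 12)
  smooth <- outer(outer(sin(pi * ax), cos(pi * ax), "+"), ax, "+") + 3
  sm <- VolumeWithMask(smooth, c(1, 1, 1), sphereMask(4)[1:12, 1:12, 1:12])
  fwd <- resampleIsotropic(sm, 0.7)
  bck <- resampleIsotropic(fwd, 1)
  m0 <- mean(intensities(sm)[maskArray(sm)])
  m1 <- mean(intensities(bck)[maskArray(bck)])
  expect_lt(abs(m1 - m0) / abs(m0), 0.01)
})

test_that("peripheral rim follows the analytic shell and subset/monotone laws", {
  m <- sphereMask(5, c(0.5, 0.5, 0.5))
  v <- VolumeWithMask(array(0, dim(m)), c(0.5, 0.5, 0.5), m)
  rim <- peripheralRim(v, 2)
  frac <- sum(maskArray(rim)) / sum(m)
  expect_lt(abs(frac - (1 - (3 / 5)^3)), 0.03)
  expect_true(all(maskArray(rim) <= m))                 # subset
  rimBig <- peripheralRim(v, 1000)
  expect_equal(maskArray(rimBig), m)                    # limit case
  # thin slab: everything within the rim
  slab <- array(FALSE, c(10, 10, 10)); slab[, , 5:6] <- TRUE
  vs <- VolumeWithMask(array(0, c(10, 10, 10)), c(1, 1, 1), slab)
  expect_equal(maskArray(peripheralRim(vs, 2)), slab)
  # monotone in rim width
  r1 <- maskArray(peripheralRim(v, 1)); r2 <- maskArray(peripheralRim(v, 2))
  expect_true(all(r1 <= r2))
  expect_error(peripheralRim(VolumeWithMask(array(0, c(4, 4, 4)),
                                            mask = array(FALSE, c(4, 4, 4)))),
               "empty")
})

test_that("gray-level discretization is exact, conservative and affine-invariant", {
  d <- c(2, 2, 1)
  v <- VolumeWithMask(array(c(0, 1, 2, 3), d), mask = array(TRUE, d))
  lv <- levelsArray(discretizeVolume(v, 4))
  expect_equal(sort(as.vector(lv)), 1:4)
  vc <- VolumeWithMask(array(7, c(3, 3, 3)))
  expect_true(all(levelsArray(discretizeVolume(vc, 16)) == 1))
  set.seed(4)
  w <- randomVolume(4)
  dz <- discretizeVolume(w, 32)
  expect_equal(sum(tabulate(levelsArray(dz)[levelsArray(dz) > 0], 32)),
               sum(maskArray(w)))
  w2 <- VolumeWithMask(7 * intensities(w) + 3, voxelSpacing(w), maskArray(w))
  expect_identical(levelsArray(discretizeVolume(w2, 32)),
                   levelsArray(discretizeVolume(w, 32)))
  expect_error(discretizeVolume(w, 1))
})
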