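test_that("class counts follow largest-remainder allocation of the prevalences", {
  counts <- largestRemainder(182, c(desert = 0.368, excluded = 0.165,
                                    inflamed = 0.467))
  expect_equal(unname(counts), c(67, 30, 85))
  expect_equal(sum(largestRemainder(97, c(0.4, 0.35, 0.25))), 97)
  spec <- cohortSpec(nPatients = 30, nResegmented = 5)
  cohort <- generateCohort(spec, seed = 2)
  expect_equal(as.integer(table(cohortPhenotypes(cohort))),
               unname(largestRemainder(30, spec$prevalence)))
})

test_that("generation is bitwise reproducible for a fixed seed", {
  spec <- cohortSpec(nPatients = 4, nResegmented = 2)
  c1 <- generateCohort(spec, seed = 99)
  c2 <- generateCohort(spec, seed = 99)
  for (i in seq_along(cohortPatients(c1))) {
    p1 <- cohortPatients(c1)[[i]]; p2 <- cohortPatients(c2)[[i]]
    expect_identical(p1@images, p2@images)
    expect_identical(p1@mask, p2@mask)
    expect_identical(p1@cd8, p2@cd8)
  }
  expect_error(cohortSpec(radiusRange = c(20, 30)), "field of view")
})

test_that("segmentation perturbation stays within the Dice and Hausdorff contract", {
  m <- sphereMask(10)
  sp <- c(1, 1, 1)
  expect_identical(perturbSegmentation(m, sp, seed = 1, jitterMm = 0, biasMm = 0), m)
  dices <- hausd <- numeric(100)
  for (s in 1:100) {
    pm <- perturbSegmentation(m, sp, seed = s)
    dices[s] <- 2 * sum(pm & m) / (sum(pm) + sum(m))
    dIn <- maskDepth(!m, sp); dOut <- maskDepth(m, sp)
    diff <- xor(pm, m)
    hausd[s] <- if (any(diff)) max(pmax(dIn, dOut)[diff]) else 0
  }
  expect_true(all(dices >= 0.80 & dices <= 0.98))
  expect_true(all(hausd <= 3))
  # second-rater masks inside a generated cohort obey the same bounds
  cohort <- generateCohort(cohortSpec(nPatients = 12, nResegmented = 6), seed = 5)
  for (pt in cohortPatients(cohort)) {
    if (!is.array(pt@secondMask)) next
    d <- 2 * sum(pt@secondMask & pt@mask) / (sum(pt@secondMask) + sum(pt@mask))
    expect_gte(d, 0.80)
    expect_lte(d, 0.98)
  }
})

test_that("CD8 densities are ordered by phenotype as generated covariates", {
  set.seed(7)
  draws <- generateCd8Densities(rep(c("desert", "excluded", "inflamed"),
                                    each = 1000))
  phen <- rep(c("desert", "excluded", "inflamed"), each = 1000)
  central <- tapply(draws$central, phen, mean)
  periph <- tapply(draws$peripheral, phen, mean)
  expect_gt(central[["inflamed"]], central[["desert"]])
  expect_gt(central[["inflamed"]], central[["excluded"]])
  expect_lt(periph[["desert"]], periph[["excluded"]])
  expect_lt(periph[["desert"]], periph[["inflamed"]])
  d1 <- generateCd8Densities("inflamed", seed = 3)
  d2 <- generateCd8Densities("inflamed", seed = 3)
  expect_identical(d1, d2)
})

test_that("the texture effect size drives a monotone dose-response in fusion AUC", {
  means <- vapply(c(0.4, 0.7, 1.0), function(eff) {
    mean(vapply(1:2, function(s) {
      rep <- suppressWarnings(
        runPipeline(cohortSpec(nPatients = 96, nResegmented = 12,
                               effectSize = eff),
                    seed = 600 + s, rois = "whole"))
      a <- rep$aucTable
      a$validationAuc[a$model == "FC"]
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("peripheral features carry the desert-vs-excluded signal at large tumor sizes", {
  tops <- lapply(c(11, 12), function(s) {
    spec <- cohortSpec(nPatients = 60,
                       prevalence = c(desert = 0.5, excluded = 0.5, inflamed = 0),
                       imageDim = c(44, 44, 38), radiusRange = c(12, 15),
                       nResegmented = 0)
    cohort <- generateCohort(spec, seed = s)
    y <- cohortPhenotypes(cohort) == "excluded"
    feats <- lapply(cohortPatients(cohort), function(pt)
      radphen:::extractPhaseRFGs(phaseVolume(pt, "dce1"), c("whole", "peri"),
                                 32, 2))
    dirAuc <- function(X) apply(X, 2, function(x)
      max(rocAuc(x, y), 1 - rocAuc(x, y)))
    top10 <- function(a) mean(sort(a, decreasing = TRUE)[1:10])
    Xw <- t(sapply(feats, function(f) f$whole))
    Xp <- t(sapply(feats, function(f) f$peri))
    c(periMax = max(dirAuc(Xp)), periTop = top10(dirAuc(Xp)),
      wholeTop = top10(dirAuc(Xw)))
  })
  for (tp in tops) {
    expect_gte(tp[["periMax"]], 0.9)
    expect_gt(tp[["periTop"]], tp[["wholeTop"]])
  }
})
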