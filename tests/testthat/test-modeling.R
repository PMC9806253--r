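test_that("cohort splitting reproduces the 3:1 arithmetic and stratification", {
  ids <- sprintf("p%03d", 1:182)
  sp <- splitCohort(ids, seed = 5)
  expect_length(sp$training, 137)
  expect_length(sp$validation, 45)
  expect_length(intersect(sp$training, sp$validation), 0)
  expect_setequal(c(sp$training, sp$validation), ids)
  expect_identical(splitCohort(ids, seed = 5), sp)       # determinism
  expect_length(splitCohort(sprintf("q%d", 1:8), seed = 1)$training, 6)
  phen <- rep(c("desert", "excluded", "inflamed"), c(67, 30, 85))
  st <- splitCohort(ids, seed = 9, stratify = phen)
  expect_length(st$training, 137)
  for (cl in unique(phen)) {
    nTr <- sum(phen[match(st$training, ids)] == cl)
    expect_lte(abs(nTr - 0.75 * sum(phen == cl)), 1)
  }
  expect_error(splitCohort(ids[1:4]), "infeasible")
})

test_that("LASSO recovers a planted informative feature among noise", {
  hits <- 0; noiseCounts <- integer()
  nestedOk <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 137
    X <- matrix(rnorm(n * 50), n, 50, dimnames = list(NULL, sprintf("f%02d", 1:50)))
    y <- rbinom(n, 1, plogis(2 * X[, 1])) == 1
    m <- fitLassoModel(X, y, seed = s)
    hits <- hits + ("f01" %in% m@features)
    noiseCounts <- c(noiseCounts, sum(m@features != "f01"))
    # nested-model property: training AUC >= best selected feature's own
    sc <- predictScore(m, X)
    best <- max(vapply(m@features, function(f)
      max(rocAuc(X[, f], y), 1 - rocAuc(X[, f], y)), 0))
    nestedOk <- nestedOk + (rocAuc(sc, y) >= best - 1e-12)
  }
  expect_gte(hits, 18)
  expect_lte(median(noiseCounts), 5)
  expect_gte(nestedOk, 18)
})

test_that("model fits are reproducible and standardization is self-contained", {
  set.seed(30)
  n <- 80
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, sprintf("g%02d", 1:20)))
  y <- rbinom(n, 1, plogis(1.5 * X[, 3] - X[, 7])) == 1
  m1 <- fitLassoModel(X, y, seed = 4)
  m2 <- fitLassoModel(X, y, seed = 4)
  expect_identical(m1@coefficients, m2@coefficients)
  expect_gt(m1@lambda, 0)
  expect_true(all(m1@coefficients != 0))
  # score depends only on stored parameters
  Xnew <- matrix(rnorm(10 * 20), 10, 20, dimnames = list(NULL, colnames(X)))
  manual <- m1@intercept +
    as.vector(scale(Xnew[, m1@features, drop = FALSE],
                    m1@center, m1@scale) %*% m1@coefficients)
  expect_equal(predictScore(m1, Xnew), manual)
})

test_that("score and feature fusion obey the redundancy and improvement laws", {
  set.seed(31)
  n <- 120
  lat1 <- rnorm(n); lat2 <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * lat1 + 1.5 * lat2)) == 1
  mods <- list(); Xs <- list()
  for (p in 1:4) {
    sig <- if (p <= 2) lat1 else lat2       # phases carry signal halves
    X <- cbind(sig + rnorm(n), matrix(rnorm(n * 9), n, 9))
    colnames(X) <- sprintf("p%d_f%02d", p, 1:10)
    Xs[[p]] <- X
    mods[[paste0("RFG", p)]] <- fitLassoModel(X, y, seed = 31 + p,
                                              source = paste0("RFG", p))
  }
  Xall <- do.call(cbind, Xs)
  sc <- combineScores(mods, Xall, y, seed = 31)
  fc <- combineFeatures(mods, Xall, y, seed = 31)
  aucSingle <- vapply(mods, function(m) rocAuc(predictScore(m, Xall), y), 0)
  aucSC <- rocAuc(predictScore(sc, Xall), y)
  aucFC <- rocAuc(predictScore(fc, Xall), y)
  expect_gte(aucSC, max(aucSingle))         # fusion of complementary halves
  expect_gte(aucFC, aucSC - 1e-12)          # FC refit at least as flexible
  expect_lte(length(fc@features), 40)       # bounded by the pooled union
  expect_identical(predictScore(sc, Xall),
                   predictScore(combineScores(mods, Xall, y, seed = 31), Xall))
  # redundant inputs: four identical phase models
  same <- list(RFG1 = mods[[1]], RFG2 = mods[[1]], RFG3 = mods[[1]],
               RFG4 = mods[[1]])
  scSame <- combineScores(same, Xall, y, seed = 31)
  expect_gte(length(scSame@features), 1)
  expect_equal(rocAuc(predictScore(scSame, Xall), y),
               rocAuc(predictScore(mods[[1]], Xall), y), tolerance = 0.02)
  expect_error(combineScores(mods[1], Xall, y), "at least two")
})

test_that("the Youden cutoff equals an exhaustive threshold scan", {
  expect_equal(optimalCutoff(c(1, 2, 8, 9), c(0, 0, 1, 1)), 5)
  for (s in 1:25) {
    set.seed(s)
    n <- sample(8:40, 1)
    sc <- round(rnorm(n), 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(y) || !any(y)) next
    cut <- optimalCutoff(sc, y)
    u <- sort(unique(sc))
    cands <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
    js <- vapply(cands, function(t) mean(sc[y] >= t) + mean(sc[!y] < t), 0)
    expect_equal(mean(sc[y] >= cut) + mean(sc[!y] < cut), max(js))
    expect_equal(cut, cands[which.max(js)])  # lowest maximizer
  }
})

test_that("the two-stage caller and its evaluation follow the cascade", {
  calls <- callPhenotype(c(2.1, 0.5, -1), c(-5, 1.2, -0.3), 2, 1)
  expect_equal(as.character(calls), c("inflamed", "excluded", "desert"))
  truth <- factor(c("inflamed", "excluded", "desert"),
                  levels = c("desert", "excluded", "inflamed"))
  ev <- evaluateCalls(calls, truth)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$macroF1, 1)
  # hand-computed confusion matrix arithmetic
  truth2 <- factor(rep(c("desert", "excluded", "inflamed"), c(9, 6, 30)),
                   levels = levels(truth))
  calls2 <- factor(c(rep("desert", 8), "excluded",
                     "desert", rep("excluded", 4), "inflamed",
                     "excluded", rep("inflamed", 29)),
                   levels = levels(truth))
  ev2 <- evaluateCalls(calls2, truth2)
  expect_equal(unname(rowSums(ev2$confusion)), c(9, 6, 30))
  expect_equal(ev2$accuracy, 41 / 45)
  expect_equal(unname(ev2$f1),
               c(16 / 18, 8 / 12, 58 / 60), tolerance = 1e-12)
  expect_equal(ev2$macroF1, mean(c(16 / 18, 8 / 12, 58 / 60)))
  expect_error(evaluateCalls(calls, truth[1:2]), "mismatch")
})

test_that("serialized models reproduce scores exactly after reload", {
  set.seed(33)
  n <- 60
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, sprintf("h%02d", 1:12)))
  y <- rbinom(n, 1, plogis(X[, 2])) == 1
  mods <- lapply(1:4, function(p) fitLassoModel(X, y, seed = p,
                                                source = paste0("RFG", p)))
  names(mods) <- paste0("RFG", 1:4)
  sc <- combineScores(mods, X, y, seed = 1)
  sc@cutoff <- optimalCutoff(predictScore(sc, X), y)
  path <- withr::local_tempfile(fileext = ".json")
  writeModelJson(sc, path)
  back <- readModelJson(path)
  Xnew <- matrix(rnorm(25 * 12), 25, 12, dimnames = list(NULL, colnames(X)))
  expect_identical(predictScore(back, Xnew), predictScore(sc, Xnew))
  expect_equal(back@cutoff, sc@cutoff)
  expect_equal(back@lambda, sc@lambda)
})
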