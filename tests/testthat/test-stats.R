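test_that("AUC follows the Mann-Whitney pair count exactly, ties included", {
  expect_equal(rocAuc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1)), 0.75)
  expect_equal(rocAuc(c(1, 2, 8, 9), c(0, 0, 1, 1)), 1.0)
  for (s in 1:30) {
    set.seed(s)
    n <- sample(8:30, 1)
    sc <- sample(1:6, n, replace = TRUE)     # heavy ties
    y <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(y) || !any(y)) next
    expect_identical(rocAuc(sc, y), bfAuc(sc, y))
  }
  set.seed(99)
  y <- rep(c(TRUE, FALSE), 1000)
  expect_lt(abs(rocAuc(rnorm(2000), y) - 0.5), 0.03)
  expect_error(rocAuc(1:4, c(1, 1, 1, 1)), "binary")
})

test_that("DeLong comparison is consistent, symmetric and matches pROC", {
  set.seed(10)
  y <- rep(c(TRUE, FALSE), c(40, 60))
  lat <- rnorm(100) + y
  a <- lat + rnorm(100); b <- lat + rnorm(100)
  dl <- delongTest(a, b, y)
  expect_equal(dl$aucA, rocAuc(a, y))
  expect_equal(dl$aucB, rocAuc(b, y))
  dlr <- delongTest(b, a, y)
  expect_equal(dl$z, -dlr$z)
  expect_equal(dl$p, dlr$p)
  # self comparison: z = 0, p = 1
  self <- delongTest(a, a, y)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  skip_if_not_installed("pROC")
  rt <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                       pROC::roc(y, b, quiet = TRUE), method = "delong")
  expect_equal(abs(dl$z), abs(unname(rt$statistic)), tolerance = 1e-8)
  expect_equal(dl$p, rt$p.value, tolerance = 1e-8)
})

test_that("DeLong variance agrees with a bootstrap of the AUC difference", {
  set.seed(42)
  n <- 150; y <- rep(c(TRUE, FALSE), c(60, 90))
  lat <- rnorm(n) + y
  a <- lat + rnorm(n); b <- lat + rnorm(n)
  dl <- delongTest(a, b, y)
  vDL <- ((dl$aucA - dl$aucB) / dl$z)^2
  bt <- replicate(2000, {
    i <- c(sample(which(y), replace = TRUE), sample(which(!y), replace = TRUE))
    rocAuc(a[i], y[i]) - rocAuc(b[i], y[i])
  })
  expect_lt(abs(vDL / var(bt) - 1), 0.10)
})

test_that("Holm adjustment equals the step-down hand computation", {
  expect_equal(holmAdjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holmAdjust(0.3), 0.3)
  expect_equal(holmAdjust(rep(0.02, 5)), rep(0.1, 5))
  expect_equal(holmAdjust(rep(0.4, 4)), rep(1, 4))
  for (s in 1:20) {
    set.seed(s)
    p <- runif(sample(2:12, 1))
    adj <- holmAdjust(p)
    expect_equal(adj, handHolm(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))   # monotone in sorted order
  }
  expect_error(holmAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("Pearson correlation matches hand covariance computation", {
  x <- 1:10
  expect_equal(pearsonCor(x, 2 * x + 1)$r, 1)
  expect_equal(pearsonCor(x, -x)$r, -1)
  xs <- c(1, 2, 4, 5, 7, 9); ys <- c(2, 1, 5, 4, 9, 8)
  r <- pearsonCor(xs, ys)
  handR <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  expect_equal(r$r, handR)
  expect_true(r$p > 0 && r$p < 1)
  expect_error(pearsonCor(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("group comparison picks t-test or ANOVA+Tukey and is calibrated", {
  g2 <- rep(c("a", "b"), each = 10)
  same <- rep(c(5, 6, 7, 8, 9), 4)
  r <- groupCompare(same, g2)
  expect_match(r$method, "t-test")
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1, tolerance = 1e-9)
  # power: two groups means 0 vs 2, sd 1, n = 30 each
  hits <- sum(vapply(1:30, function(s) {
    set.seed(s)
    groupCompare(c(rnorm(30), rnorm(30, 2)), rep(1:2, each = 30))$p < 0.001
  }, NA))
  expect_gte(hits, ceiling(0.95 * 30))
  # 3-group ANOVA F against hand sum-of-squares decomposition
  vals <- c(1, 2, 3, 5, 6, 7, 2, 4, 6)
  grp <- rep(c("x", "y", "z"), each = 3)
  r3 <- groupCompare(vals, grp)
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(vals, grp, function(v) sum((v - mean(v))^2)))
  Fhand <- (ssb / 2) / (ssw / 6)
  expect_equal(r3$statistic, Fhand, tolerance = 1e-10)
  expect_true(is.matrix(r3$tukey) && nrow(r3$tukey) == 3)
})

test_that("ICC(2,1) matches the aov decomposition and its invariances", {
  ident <- cbind(c(1, 2, 3, 4, 7), c(1, 2, 3, 4, 7))
  expect_equal(icc2wayRandom(ident), 1)
  r4 <- cbind(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(icc2wayRandom(r4), aovIcc(r4), tolerance = 1e-10)
  for (s in 1:10) {
    set.seed(s)
    m <- matrix(rnorm(20), 10, 2) + rnorm(10)
    expect_equal(icc2wayRandom(m), aovIcc(m), tolerance = 1e-9)
    expect_equal(icc2wayRandom(m + 5), icc2wayRandom(m), tolerance = 1e-9)
    expect_equal(icc2wayRandom(3 * m), icc2wayRandom(m), tolerance = 1e-9)
  }
  # shuffled columns: mean ICC near zero
  set.seed(11)
  base <- rnorm(15, sd = 2)
  iccs <- vapply(1:200, function(i) {
    icc2wayRandom(cbind(sample(base), sample(base)))
  }, 0)
  expect_lt(abs(mean(iccs)), 0.1)
  expect_warning(icc2wayRandom(matrix(1, 5, 2)), "between-subject")
})
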