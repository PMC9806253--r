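#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' AUC computed from ranks, equivalent to the proportion of
#' (positive, negative) pairs in which the positive sample scores higher,
#' with 0.5 credit for ties.
#'
#' @param scores numeric predictor.
#' @param labels binary outcome (logical, 0/1, or a two-level factor whose
#'   second level is taken as positive).
#' @return AUC in `[0, 1]`.
#' @examples
#' rocAuc(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1)) # 0.75
#' @export
rocAuc <- function(scores, labels) {
  y <- asBinary(labels)
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

asBinary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) {
    if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
    return(labels == levels(labels)[2])
  }
  u <- sort(unique(labels))
  if (length(u) != 2L) stop("labels must be binary")
  labels == u[2]
}

#' DeLong test comparing two correlated AUCs
#'
#' Paired comparison of the AUCs of two score vectors measured on the same
#' subjects, using the DeLong placement-component (structural) covariance
#' and a two-sided normal p-value.
#'
#' @param scoresA,scoresB numeric scores for the same subjects.
#' @param labels binary outcome.
#' @return A list of class `"aucComparison"` with elements `aucA`, `aucB`,
#'   `z` and `p`.
#' @export
delongTest <- function(scoresA, scoresB, labels) {
  if (length(scoresA) != length(scoresB) || length(scoresA) != length(labels))
    stop("paired comparison requires equal-length inputs")
  y <- asBinary(labels)
  pos <- which(y); neg <- which(!y)
  m <- length(pos); n <- length(neg)
  if (m == 0 || n == 0) stop("both classes must be present")
  placements <- function(s) {
    X <- s[pos]; Y <- s[neg]
    # psi(X_i, Y_j): 1 if X > Y, 0.5 ties, 0 otherwise
    cmp <- outer(X, Y, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
  }
  pa <- placements(scoresA); pb <- placements(scoresB)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  vr <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  diff <- pa$auc - pb$auc
  if (!is.finite(vr) || vr <= .Machine$double.eps) {
    if (abs(diff) > 0)
      warning("degenerate placement variance with unequal AUCs")
    else if (!identical(scoresA, scoresB))
      warning("degenerate placement variance; p-value set to 1")
    z <- 0; p <- 1
  } else {
    z <- diff / sqrt(vr)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(aucA = pa$auc, aucB = pb$auc, z = z, p = p),
            class = "aucComparison")
}

#' @export
print.aucComparison <- function(x, ...) {
  cat(sprintf("DeLong AUC comparison: %.4f vs %.4f (z = %.3f, p = %.4g)\n",
              x$aucA, x$aucB, x$z, x$p))
  invisible(x)
}

#' Holm step-down adjustment of p-values
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holmAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Pearson product-moment correlation with t-distributed p-value
#'
#' @param x,y numeric vectors (n >= 3, nonzero variance).
#' @return A list with elements `r` and `p`.
#' @export
pearsonCor <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) stop("need paired n >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Compare a continuous variable between groups
#'
#' Two groups: t-test (Welch by default; set `varEqual = TRUE` for the
#' pooled-variance form). More than two groups: one-way ANOVA with a
#' post-hoc Tukey HSD pairwise table.
#'
#' @param values numeric.
#' @param groups grouping vector (coerced to factor), each group n >= 2.
#' @param varEqual use the pooled-variance t-test for two groups.
#' @return A list with `method`, `statistic`, `p` and, for ANOVA, `tukey`
#'   (the pairwise comparison table).
#' @export
groupCompare <- function(values, groups, varEqual = FALSE) {
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("every group needs n >= 2")
  if (nlevels(g) == 2) {
    tt <- t.test(values ~ g, var.equal = varEqual)
    list(method = if (varEqual) "t-test" else "Welch t-test",
         statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    fit <- aov(values ~ g)
    s <- summary(fit)[[1]]
    list(method = "one-way ANOVA + Tukey HSD",
         statistic = s[["F value"]][1], p = s[["Pr(>F)"]][1],
         tukey = TukeyHSD(fit)$g)
  }
}

#' Two-way random-effects single-rater absolute-agreement ICC(2,1)
#'
#' The intraclass correlation from the two-way ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with subjects as
#' rows and raters as columns. Used to keep only segmentation-stable
#' radiomic features.
#'
#' @param ratings numeric matrix, n subjects x k raters (n >= 3, k >= 2).
#' @return ICC value; 0 with a warning when between-subject variance is
#'   zero (agreement undefined).
#' @export
icc2wayRandom <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 raters")
  if (any(!is.finite(ratings))) stop("ratings must be finite")
  m <- mean(ratings)
  ri <- rowMeans(ratings); cj <- colMeans(ratings)
  ssr <- k * sum((ri - m)^2)
  ssc <- n * sum((cj - m)^2)
  sst <- sum((ratings - m)^2)
  sse <- max(sst - ssr - ssc, 0)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (ssr <= .Machine$double.eps * max(1, sst) || denom <= 0) {
    warning("zero between-subject variance: agreement undefined, returning 0")
    return(0)
  }
  (msr - mse) / denom
}
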