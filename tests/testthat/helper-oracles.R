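# Independent brute-force oracles the implementation is checked against.
# These deliberately use different algorithms (explicit loops, rle, BFS,
# aov) from the package's kernels.

bfGlcmCounts <- function(levels, G, dirs, dist = 1) {
  d <- dim(levels)
  C <- matrix(0, G, G)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- levels[i, j, k]
    if (a == 0) next
    for (r in seq_len(nrow(dirs))) {
      i2 <- i + dirs[r, 1] * dist; j2 <- j + dirs[r, 2] * dist
      k2 <- k + dirs[r, 3] * dist
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
      b <- levels[i2, j2, k2]
      if (b == 0) next
      C[a, b] <- C[a, b] + 1
      C[b, a] <- C[b, a] + 1
    }
  }
  C
}

# run-length counts via rle over explicitly enumerated lines
bfGlrlmCounts <- function(levels, G, dir) {
  d <- dim(levels)
  runs <- list()
  # line start points: voxels whose predecessor along dir is out of bounds
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    pi <- i - dir[1]; pj <- j - dir[2]; pk <- k - dir[3]
    if (pi >= 1 && pi <= d[1] && pj >= 1 && pj <= d[2] && pk >= 1 && pk <= d[3])
      next
    line <- integer()
    ci <- i; cj <- j; ck <- k
    while (ci >= 1 && ci <= d[1] && cj >= 1 && cj <= d[2] && ck >= 1 && ck <= d[3]) {
      line <- c(line, levels[ci, cj, ck])
      ci <- ci + dir[1]; cj <- cj + dir[2]; ck <- ck + dir[3]
    }
    r <- rle(line)
    keep <- r$values > 0
    if (any(keep)) runs[[length(runs) + 1]] <- cbind(r$values[keep], r$lengths[keep])
  }
  runs <- do.call(rbind, runs)
  if (is.null(runs)) return(matrix(0, G, 1))
  M <- matrix(0, G, max(runs[, 2]))
  for (q in seq_len(nrow(runs)))
    M[runs[q, 1], runs[q, 2]] <- M[runs[q, 1], runs[q, 2]] + 1
  M
}

# zone sizes via BFS flood fill with an explicit queue
bfGlszmCounts <- function(levels, G) {
  d <- dim(levels)
  seen <- array(FALSE, d)
  zones <- list()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    lev <- levels[i, j, k]
    if (lev == 0 || seen[i, j, k]) next
    queue <- matrix(c(i, j, k), 1)
    seen[i, j, k] <- TRUE
    size <- 0
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        p <- cur + offs[r, ]
        if (any(p < 1) || any(p > d)) next
        if (!seen[p[1], p[2], p[3]] && levels[p[1], p[2], p[3]] == lev) {
          seen[p[1], p[2], p[3]] <- TRUE
          queue <- rbind(queue, p)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  zones <- do.call(rbind, zones)
  M <- matrix(0, G, max(zones[, 2]))
  for (q in seq_len(nrow(zones)))
    M[zones[q, 1], zones[q, 2]] <- M[zones[q, 1], zones[q, 2]] + 1
  M
}

bfNgtdm <- function(levels, G) {
  d <- dim(levels)
  n_i <- numeric(G); s_i <- numeric(G)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    a <- levels[i, j, k]
    if (a == 0) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      i2 <- i + dx; j2 <- j + dy; k2 <- k + dz
      if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
      b <- levels[i2, j2, k2]
      if (b > 0) nb <- c(nb, b)
    }
    if (length(nb) == 0) next
    n_i[a] <- n_i[a] + 1
    s_i[a] <- s_i[a] + abs(a - mean(nb))
  }
  list(n = n_i, s = s_i)
}

bfAuc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (x in pos) for (y in neg)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(pos) * length(neg))
}

# ICC(2,1) via R's aov decomposition rather than direct sums
aovIcc <- function(ratings) {
  n <- nrow(ratings); k <- ncol(ratings)
  df <- data.frame(y = as.vector(ratings),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

handHolm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  run <- 0
  for (i in seq_len(m)) {
    run <- max(run, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, run)
  }
  adj
}

# literal-formula GLCM features, second implementation with explicit loops
glcmFeatureOracle <- function(P) {
  G <- nrow(P)
  mux <- 0
  for (a in 1:G) for (b in 1:G) mux <- mux + a * P[a, b]
  varx <- 0
  for (a in 1:G) for (b in 1:G) varx <- varx + (a - mux)^2 * P[a, b]
  out <- c(contrast = 0, dissimilarity = 0, homogeneity = 0, energy = 0,
           entropy = 0, correlation = 0, cluster_shade = 0,
           cluster_prominence = 0, max_probability = 0, sum_average = 0,
           sum_entropy = 0, difference_entropy = 0, idn = 0)
  psum <- numeric(2 * G); pdif <- numeric(G)
  for (a in 1:G) for (b in 1:G) {
    p <- P[a, b]
    out["contrast"] <- out["contrast"] + (a - b)^2 * p
    out["dissimilarity"] <- out["dissimilarity"] + abs(a - b) * p
    out["homogeneity"] <- out["homogeneity"] + p / (1 + (a - b)^2)
    out["energy"] <- out["energy"] + p^2
    if (p > 0) out["entropy"] <- out["entropy"] - p * log2(p)
    out["correlation"] <- out["correlation"] + a * b * p
    out["cluster_shade"] <- out["cluster_shade"] + (a + b - 2 * mux)^3 * p
    out["cluster_prominence"] <- out["cluster_prominence"] + (a + b - 2 * mux)^4 * p
    out["max_probability"] <- max(out["max_probability"], p)
    out["idn"] <- out["idn"] + p / (1 + abs(a - b) / G)
    psum[a + b] <- psum[a + b] + p
    pdif[abs(a - b) + 1] <- pdif[abs(a - b) + 1] + p
  }
  out["correlation"] <- if (varx > 0) (out["correlation"] - mux^2) / varx else 1
  for (k in 2:(2 * G)) {
    out["sum_average"] <- out["sum_average"] + k * psum[k]
    if (psum[k] > 0) out["sum_entropy"] <- out["sum_entropy"] - psum[k] * log2(psum[k])
  }
  for (k in 1:G)
    if (pdif[k] > 0) out["difference_entropy"] <- out["difference_entropy"] - pdif[k] * log2(pdif[k])
  names(out) <- paste0("glcm_", names(out))
  out
}
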