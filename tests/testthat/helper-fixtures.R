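# fixtures generated in code at test time

randLevels <- function(seed, dims = c(8, 8, 8), G = 6, pMask = 0.75) {
  set.seed(seed)
  lev <- array(sample.int(G, prod(dims), replace = TRUE), dims)
  lev[runif(prod(dims)) >= pMask] <- 0L
  storage.mode(lev) <- "integer"
  lev
}

discFromLevels <- function(lev, G, spacing = c(1, 1, 1)) {
  methods::new("DiscretizedVolume", levels = lev, nLevels = as.integer(G),
               spacing = spacing)
}

sphereMask <- function(radiusMm, spacing = c(1, 1, 1), marginMm = 2) {
  d <- ceiling((2 * (radiusMm + marginMm)) / spacing) + 1
  ctr <- (d - 1) / 2 * spacing
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * spacing[a] - ctr[a])
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+")
  r2 <= radiusMm^2
}

randomVolume <- function(seed, dims = c(10, 10, 8), spacing = c(1, 1, 1),
                         pMask = 0.8) {
  set.seed(seed)
  mask <- array(runif(prod(dims)) < pMask, dims)
  if (!any(mask)) mask[1] <- TRUE
  VolumeWithMask(array(rnorm(prod(dims)), dims), spacing, mask)
}

# small shared pipeline fixture, built once per test run
.fixtureEnv <- new.env()
miniReport <- function() {
  if (is.null(.fixtureEnv$report)) {
    spec <- cohortSpec(nPatients = 60, nResegmented = 10)
    .fixtureEnv$report <- suppressWarnings(runPipeline(spec, seed = 77))
  }
  .fixtureEnv$report
}
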