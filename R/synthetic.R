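PHENOTYPES <- c("desert", "excluded", "inflamed")

#' Settings for a synthetic DCE-MRI phantom cohort
#'
#' Defines the study conditions the generator emulates: cohort size and
#' phenotype prevalences, image geometry, four-phase enhancement kinetics
#' with wash-out, phenotype-dependent speckle texture localized to the
#' tumor core vs the 2-mm rim, acquisition noise, and the re-segmented
#' subset used for stability filtering.
#'
#' @param nPatients cohort size (default 182).
#' @param prevalence phenotype prevalences, summing to 1 (default
#'   36.8/16.5/46.7% for desert/excluded/inflamed).
#' @param imageDim voxel grid (default 32 x 32 x 26).
#' @param spacing voxel spacing in mm (default 1 mm isotropic).
#' @param radiusRange range of ellipsoid semi-axes in mm.
#' @param rimMm rim thickness defining the tumor periphery (default 2).
#' @param enhancement relative enhancement of phases DCE_1..DCE_4: strongest
#'   wash-in on the first post-contrast phase, then wash-out, so the early
#'   phase carries the most texture signal against the fixed noise floor.
#' @param preScale relative enhancement of the pre-contrast image.
#' @param coreAmplitude,rimAmplitude per-phenotype speckle amplitude in the
#'   tumor core / the 2-mm rim (relative to the phase enhancement): the
#'   inflamed phantom carries speckle throughout, the excluded phantom only
#'   in the rim, and the desert phantom is smooth everywhere.
#' @param corePersistence,rimPersistence per-phenotype texture wash-out
#'   kinetics: the multiplicative change of the speckle amplitude per phase
#'   (values below 1 wash out, above 1 persist and accumulate). A single
#'   phase cannot observe a rate of change, so this kinetic contrast is
#'   the component of the phenotype signal that only multi-phase fusion
#'   recovers.
#' @param effectSize scales the log-amplitude contrast between phenotypes;
#'   0 gives a null cohort with no phenotype-texture coupling.
#' @param globalSdLog patient-level lognormal sd of the overall texture
#'   amplitude, shared by both regions and all phases: the dominant
#'   between-patient nuisance that caps what any single-phase level can
#'   discriminate, while phase-difference (kinetic) contrasts cancel it.
#' @param patientSdLog patient-level lognormal sd of texture amplitude per
#'   region (core and rim drawn independently, shared across phases).
#' @param phaseSdLog phase-level lognormal sd of texture amplitude
#'   (independent per phase, so multi-phase fusion averages it out).
#' @param noiseSd additive Gaussian acquisition noise sd (all phases).
#' @param speckleSigmaVox Gaussian correlation length of the speckle field
#'   in voxels.
#' @param nResegmented patients re-segmented by the second rater (default 20).
#' @param segJitterMm boundary jitter amplitude of the second-rater
#'   segmentation in mm.
#' @param cd8MeanLog per-phenotype lognormal meanlog of the stromal CD8+
#'   densities (central and peripheral, cells/mm^2).
#' @param cd8SdLog lognormal sdlog of the CD8+ densities.
#' @return A list of generator settings (class `"cohortSpec"`).
#' @export
cohortSpec <- function(nPatients = 182,
                       prevalence = c(desert = 0.368, excluded = 0.165,
                                      inflamed = 0.467),
                       imageDim = c(32, 32, 26),
                       spacing = c(1, 1, 1),
                       radiusRange = c(5, 9),
                       rimMm = 2,
                       enhancement = c(3.0, 2.4, 1.9, 1.5),
                       preScale = 0.3,
                       coreAmplitude = c(desert = 0.13, excluded = 0.13,
                                         inflamed = 0.72),
                       rimAmplitude = c(desert = 0.13, excluded = 0.52,
                                        inflamed = 0.52),
                       corePersistence = c(desert = 0.9, excluded = 0.9,
                                           inflamed = 0.9),
                       rimPersistence = c(desert = 0.9, excluded = 0.9,
                                          inflamed = 0.9),
                       effectSize = 1,
                       globalSdLog = 0.1,
                       patientSdLog = 0.15,
                       phaseSdLog = 0.7,
                       noiseSd = 0.3,
                       speckleSigmaVox = 0.8,
                       nResegmented = 20,
                       segJitterMm = 0.6,
                       cd8MeanLog = list(central = c(desert = log(40),
                                                     excluded = log(55),
                                                     inflamed = log(260)),
                                         peripheral = c(desert = log(25),
                                                        excluded = log(230),
                                                        inflamed = log(210))),
                       cd8SdLog = 0.5) {
  if (abs(sum(prevalence) - 1) > 1e-6) stop("prevalences must sum to 1")
  if (nResegmented > nPatients) stop("nResegmented cannot exceed nPatients")
  if (2 * max(radiusRange) + 6 > min(imageDim * spacing))
    stop("infeasible geometry: tumor larger than the field of view")
  spec <- list(nPatients = as.integer(nPatients), prevalence = prevalence,
               imageDim = as.integer(imageDim), spacing = spacing,
               radiusRange = radiusRange, rimMm = rimMm,
               enhancement = enhancement, preScale = preScale,
               coreAmplitude = coreAmplitude, rimAmplitude = rimAmplitude,
               corePersistence = corePersistence,
               rimPersistence = rimPersistence,
               effectSize = effectSize, globalSdLog = globalSdLog,
               patientSdLog = patientSdLog,
               phaseSdLog = phaseSdLog, noiseSd = noiseSd,
               speckleSigmaVox = speckleSigmaVox,
               nResegmented = as.integer(nResegmented),
               segJitterMm = segJitterMm,
               cd8MeanLog = cd8MeanLog, cd8SdLog = cd8SdLog)
  class(spec) <- c("cohortSpec", "list")
  spec
}

#' Largest-remainder allocation of class counts
#'
#' @param n total count.
#' @param prop proportions summing to 1.
#' @return Integer counts summing to `n`.
#' @export
largestRemainder <- function(n, prop) {
  target <- n * prop
  base <- floor(target)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  out <- as.integer(base)
  names(out) <- names(prop)
  out
}

# phenotype amplitudes after applying the effect-size scaling on log scale:
# effectSize 0 collapses all classes onto the smallest amplitude
scaledAmplitudes <- function(amp, effectSize) {
  low <- min(amp)
  exp(log(low) + effectSize * (log(amp) - log(low)))
}

# persistence scaled toward the desert (reference) kinetics; effectSize 0
# removes the kinetic class contrast entirely
scaledPersistence <- function(per, effectSize) {
  ref <- per[["desert"]]
  exp(log(ref) + effectSize * (log(per) - log(ref)))
}

speckleField <- function(dim, sigma) {
  f <- cpp_smooth_gauss(array(rnorm(prod(dim)), dim), sigma)
  f / sd(f)
}

#' Generate one synthetic phantom patient
#'
#' An ellipsoidal tumor with a smooth enhancement dome, phenotype-dependent
#' speckle texture (inflamed: core and rim; excluded: rim only; desert:
#' none), four post-contrast phases with wash-out kinetics plus a
#' pre-contrast image, additive acquisition noise, and generated stromal
#' CD8+ density covariates.
#'
#' @param spec a [cohortSpec()].
#' @param phenotype one of `"desert"`, `"excluded"`, `"inflamed"`.
#' @param seed integer seed for this patient.
#' @param id patient identifier.
#' @param resegment also generate a second-rater segmentation.
#' @return A [SyntheticPatient-class].
#' @export
generatePatient <- function(spec, phenotype, seed, id = "pt", resegment = FALSE) {
  phenotype <- match.arg(phenotype, PHENOTYPES)
  set.seed(seed)
  d <- spec$imageDim; sp <- spec$spacing
  semi <- runif(3, spec$radiusRange[1], spec$radiusRange[2])
  semi <- pmin(semi, d * sp / 2 - 3)
  ctr <- (d - 1) * sp / 2 + runif(3, -1.5, 1.5)
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  rho2 <- outer(outer(((x - ctr[1]) / semi[1])^2,
                      ((y - ctr[2]) / semi[2])^2, "+"),
                ((z - ctr[3]) / semi[3])^2, "+")
  mask <- rho2 <= 1
  depth <- maskDepth(mask, sp)
  rimRegion <- mask & depth <= spec$rimMm
  coreRegion <- mask & !rimRegion
  dome <- (0.6 + 0.4 * pmax(1 - rho2, 0)) * mask

  ampCore <- scaledAmplitudes(spec$coreAmplitude, spec$effectSize)[[phenotype]]
  ampRim <- scaledAmplitudes(spec$rimAmplitude, spec$effectSize)[[phenotype]]
  perCore <- scaledPersistence(spec$corePersistence, spec$effectSize)[[phenotype]]
  perRim <- scaledPersistence(spec$rimPersistence, spec$effectSize)[[phenotype]]
  # patient-level nuisances shared across phases: one global amplitude
  # factor plus independent per-region factors
  uGlobal <- exp(rnorm(1, 0, spec$globalSdLog))
  uCore <- uGlobal * exp(rnorm(1, 0, spec$patientSdLog))
  uRim <- uGlobal * exp(rnorm(1, 0, spec$patientSdLog))

  images <- vector("list", 5)
  names(images) <- c("pre", paste0("dce", 1:4))
  images[["pre"]] <- 0.15 + spec$preScale * dome +
    array(rnorm(prod(d), 0, spec$noiseSd), d)
  for (p in 1:4) {
    e <- spec$enhancement[p]
    # phase-level jitter, independent per region, averaged out by fusion
    jC <- exp(rnorm(1, 0, spec$phaseSdLog))
    jR <- exp(rnorm(1, 0, spec$phaseSdLog))
    ampMap <- ampCore * perCore^(p - 1) * uCore * jC * coreRegion +
      ampRim * perRim^(p - 1) * uRim * jR * rimRegion
    S <- speckleField(d, spec$speckleSigmaVox)
    images[[p + 1]] <- 0.15 + e * dome + e * ampMap * S +
      array(rnorm(prod(d), 0, spec$noiseSd), d)
  }

  second <- if (resegment)
    perturbSegmentation(mask, sp, seed = seed + 1L,
                        jitterMm = spec$segJitterMm) else list()
  cd8 <- generateCd8Densities(phenotype, spec = spec)
  new("SyntheticPatient", id = id, phenotype = phenotype, images = images,
      mask = mask, secondMask = second, spacing = sp,
      cd8 = c(central = cd8$central, peripheral = cd8$peripheral))
}

#' Generate a synthetic phantom cohort
#'
#' Phenotype counts follow the spec prevalences by largest-remainder
#' allocation; a random subset of patients receives a second-rater
#' segmentation. Reproducible: the same seed yields bitwise-identical
#' volumes.
#'
#' @param spec a [cohortSpec()].
#' @param seed integer master seed.
#' @return A [SyntheticCohort-class].
#' @export
generateCohort <- function(spec = cohortSpec(), seed = 20221219) {
  seed <- as.integer(seed)
  n <- spec$nPatients
  counts <- largestRemainder(n, spec$prevalence)
  set.seed(seed)
  phen <- sample(rep(PHENOTYPES, counts))
  ids <- sprintf("pt%03d", seq_len(n))
  resegIds <- sample(ids, spec$nResegmented)
  patientSeeds <- sample.int(.Machine$integer.max - 1L, n)
  patients <- lapply(seq_len(n), function(i) {
    generatePatient(spec, phen[i], patientSeeds[i], id = ids[i],
                    resegment = ids[i] %in% resegIds)
  })
  names(patients) <- ids
  new("SyntheticCohort", patients = patients, spec = unclass(spec),
      seed = seed)
}

#' Perturb a segmentation to emulate a second rater
#'
#' Adds a smooth random field (plus a global dilation/erosion bias) to the
#' signed distance of the mask boundary and re-thresholds. The jitter scale
#' is calibrated per case (deterministically, from the seed) so that the
#' Dice overlap with the input lands in the inter-rater agreement band
#' `[0.82, 0.97]` regardless of lesion size or voxel quantization — a
#' plausibly different delineation of the same lesion, never a trivially
#' identical or wildly different one. Zero jitter reproduces the mask
#' exactly.
#'
#' @param mask 3D logical array (non-empty).
#' @param spacing voxel spacing in mm.
#' @param seed integer seed.
#' @param jitterMm initial boundary jitter amplitude in mm (default 0.6);
#'   0 together with `biasMm = 0` disables the perturbation.
#' @param biasMm maximum global dilation/erosion bias in mm (default 0.3);
#'   the drawn bias magnitude lies in `[biasMm/2, biasMm]` with random sign.
#' @return Perturbed 3D logical mask.
#' @export
perturbSegmentation <- function(mask, spacing, seed = 1, jitterMm = 0.6,
                                biasMm = 0.3) {
  if (!any(mask)) stop("empty input mask")
  set.seed(seed)
  if (jitterMm == 0 && biasMm == 0) return(mask)
  din <- maskDepth(mask, spacing)
  dout <- maskDepth(!mask, spacing)
  phi <- din - dout
  g <- cpp_smooth_gauss(array(rnorm(prod(dim(mask))), dim(mask)), 2.0)
  band <- abs(phi) <= 3
  g <- g / sd(g[band])   # unit field strength where it can move the boundary
  b <- if (biasMm > 0) sample(c(-1, 1), 1) * runif(1, biasMm / 2, biasMm) else
    jitterMm / 2
  scale <- 1
  out <- mask
  for (i in 1:30) {
    # clamp the boundary displacement so the second rater never strays more
    # than ~3 mm from the original surface (Hausdorff bound)
    delta <- pmin(pmax(scale * (jitterMm * g + b), -2.9), 2.9)
    out <- (phi + delta) > 0
    if (!any(out)) stop("perturbation emptied the mask")
    dice <- 2 * sum(out & mask) / (sum(out) + sum(mask))
    if (dice > 0.97) scale <- scale * 1.3
    else if (dice < 0.82) scale <- scale / 1.3
    else break
  }
  out
}

#' Generate stromal CD8+ density covariates
#'
#' Log-normal draws with phenotype-specific means: the inflamed phenotype
#' has the highest central density, the desert phenotype the lowest
#' peripheral density (excluded and inflamed are similar peripherally).
#' These are generated covariates, not derived from the images; their
#' correlation with radiomic scores arises through the shared phenotype.
#'
#' @param phenotype character vector of phenotypes.
#' @param seed optional integer seed.
#' @param spec a [cohortSpec()] supplying the lognormal parameters.
#' @return A list with numeric vectors `central` and `peripheral`
#'   (cells/mm^2).
#' @export
generateCd8Densities <- function(phenotype, seed = NULL, spec = cohortSpec()) {
  phenotype <- match.arg(phenotype, PHENOTYPES, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(phenotype)
  list(central = rlnorm(n, spec$cd8MeanLog$central[phenotype], spec$cd8SdLog),
       peripheral = rlnorm(n, spec$cd8MeanLog$peripheral[phenotype],
                           spec$cd8SdLog))
}
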