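#' Default log-spaced q grid over the instrument's total range
#'
#' @param qMin,qMax range in 1/A (default 0.002-0.3).
#' @param binsPerDecade grid density (default 40).
#' @return numeric vector of q values.
#' @export
defaultQGrid <- function(qMin = 0.002, qMax = 0.3, binsPerDecade = 40L) {
  n <- ceiling(log10(qMax / qMin) * binsPerDecade)
  10^seq(log10(qMin), log10(qMax), length.out = n + 1L)
}

# documented counter scheme: child seed i of master seed s
.childSeed <- function(seed, i) {
  (as.integer(seed) + 7919L * as.integer(i)) %% .Machine$integer.max
}

#' Generate a synthetic 1D equatorial profile with known ground truth
#'
#' I_obs = I_model * (1 + noiseLevel * eps) with eps standard normal, and
#' sigma = noiseLevel * I_model. Seeded; the ground truth is stored in the
#' profile metadata.
#'
#' @param truth a [WoodModelParams-class].
#' @param qGrid q values, 1/A (default [defaultQGrid()]).
#' @param noiseLevel fractional noise level >= 0 (0 gives the exact model).
#' @param seed integer seed.
#' @return a [Profile1D-class]; \code{meta$truth} holds \code{truth},
#'   \code{meta$noiseLevel} and \code{meta$seed} the generator settings.
#' @examples
#' prof <- generateProfile(WoodModelParams(), noiseLevel = 0.02, seed = 1)
#' @export
generateProfile <- function(truth, qGrid = defaultQGrid(),
                            noiseLevel = 0.02, seed = 1L) {
  validObject(truth)
  stopifnot(noiseLevel >= 0)
  Im <- totalIntensity(qGrid, truth)
  set.seed(as.integer(seed))
  eps <- stats::rnorm(length(qGrid))
  Profile1D(q = qGrid, I = Im * (1 + noiseLevel * eps),
            sigma = noiseLevel * Im,
            meta = list(truth = truth, noiseLevel = noiseLevel, seed = seed))
}

# wrapped-Gaussian azimuthal weight, normalised to unit mean over azimuth.
# `eqd` is the folded angular distance from the equator in [0, 90] degrees.
.azimuthWeight <- function(eqd, spread) {
  # two streaks per full circle (0 and 180 deg); the fold maps both onto
  # eqd ~ 0, the second term handles the wrap at 90 deg
  w <- exp(-eqd^2 / (2 * spread^2)) + exp(-(180 - eqd)^2 / (2 * spread^2))
  w * 180 / (sqrt(2 * pi) * spread)
}

#' Expected (noise-free) pixel intensity maps for a synthetic frame
#'
#' Anisotropic terms (microfibril packing, bundle Gaussian, oriented power
#' law) are multiplied by a wrapped-Gaussian azimuthal weight centered on
#' the equator and normalised to unit mean over azimuth; an isotropic flat
#' plus optional q^-4 term is added. The result is scaled by
#' countsScale * exposure * cos^3(2 theta).
#'
#' @param spec a [SyntheticSpec-class].
#' @param geometry one [Geometry-class] from the spec.
#' @return list with matrices \code{lambda} (expected counts),
#'   \code{anisotropic} and \code{isotropic} (expected counts split by
#'   component), the q map, and the beam-stop \code{mask}.
#' @export
expectedFrame <- function(spec, geometry) {
  validObject(spec)
  qm <- buildQMap(geometry, spec@frameShape)
  q <- pmax(qm$q, 1e-6)
  t <- spec@truth
  Ian <- totalIntensity(as.numeric(q),
                        paramsFromVector(`[<-`(paramsToVector(t), "C_bg", 0)))
  Ian <- matrix(Ian, nrow(q), ncol(q))
  w <- .azimuthWeight(qm$equatorDist, spec@orientationSpread)
  Iiso <- spec@isoFlat + t@C_bg +
    if (spec@isoPorod > 0) spec@isoPorod * q^-4 else 0
  sc <- spec@countsScale * spec@exposure * qm$solidAngle
  # beam-stop mask: 3-pixel radius around the direct beam
  nr <- spec@frameShape[1]; nc <- spec@frameShape[2]
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rpix <- sqrt((row - geometry@beamCenter[1])^2 +
               (col - geometry@beamCenter[2])^2)
  list(lambda = sc * (w * Ian + Iiso),
       anisotropic = sc * w * Ian, isotropic = sc * Iiso,
       qmap = qm, mask = rpix < 3)
}

#' Generate synthetic multi-distance detector frames
#'
#' One Poisson-noisy [DetectorFrame-class] per geometry in the spec, from
#' the expected-intensity maps of [expectedFrame()]. Child seeds derive
#' from the master seed by a fixed counter scheme (seed + 7919 * i), so
#' frames are independently and reproducibly seeded.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with \code{frames} (list of [DetectorFrame-class]),
#'   \code{truth} (the spec), and \code{expected} (per-frame
#'   [expectedFrame()] output, for oracle checks).
#' @examples
#' \donttest{
#' sim <- generateFrames(SyntheticSpec(seed = 3))
#' sim$frames[[1]]
#' }
#' @export
generateFrames <- function(spec) {
  validObject(spec)
  expected <- lapply(spec@geometries, function(g) expectedFrame(spec, g))
  frames <- vector("list", length(expected))
  for (i in seq_along(expected)) {
    e <- expected[[i]]
    set.seed(.childSeed(spec@seed, i))
    counts <- matrix(stats::rpois(length(e$lambda), e$lambda),
                     nrow(e$lambda), ncol(e$lambda))
    frames[[i]] <- DetectorFrame(counts, spec@geometries[[i]],
                                 exposure = spec@exposure, mask = e$mask)
  }
  list(frames = frames, truth = spec, expected = expected)
}

#' Reduce and merge synthetic (or real) frames to one equatorial profile
#'
#' Convenience pipeline: [separateAnisotropic()] on every frame, then
#' [mergeProfiles()].
#'
#' @param frames list of [DetectorFrame-class].
#' @param sectors a [SectorSpec-class].
#' @param binsPerDecade q-bin density.
#' @return merged equatorial [Profile1D-class].
#' @export
reduceFrames <- function(frames, sectors = SectorSpec(),
                         binsPerDecade = 40L) {
  profs <- lapply(frames, separateAnisotropic, sectors = sectors,
                  binsPerDecade = binsPerDecade)
  mergeProfiles(profs, binsPerDecade = binsPerDecade)
}

#' Write a regenerable synthetic fixture set
#'
#' Writes every frame (text counts + YAML geometry sidecar + mask), the
#' ground truth as JSON, and a manifest listing each file with its MD5
#' hash together with the generator seed. Regenerating from the same spec
#' reproduces identical hashes.
#'
#' @param spec a [SyntheticSpec-class].
#' @param outDir destination directory (created if needed).
#' @return the manifest, invisibly (list with \code{files}, \code{md5},
#'   \code{seed}).
#' @export
writeFixtureSet <- function(spec, outDir) {
  validObject(spec)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  sim <- generateFrames(spec)
  files <- character()
  for (i in seq_along(sim$frames)) {
    f <- file.path(outDir, sprintf("frame_%02d.txt", i))
    files <- c(files, writeFrame(sim$frames[[i]], f))
  }
  truthFile <- file.path(outDir, "truth.json")
  jsonlite::write_json(
    list(params = as.list(paramsToVector(spec@truth)),
         orientation_spread = spec@orientationSpread,
         iso_flat = spec@isoFlat, iso_porod = spec@isoPorod,
         counts_scale = spec@countsScale, exposure = spec@exposure,
         frame_shape = spec@frameShape, seed = spec@seed),
    truthFile, auto_unbox = TRUE, digits = NA)
  files <- c(files, truthFile)
  manifest <- list(files = basename(files),
                   md5 = as.character(tools::md5sum(files)),
                   seed = spec@seed)
  manifestFile <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestFile, auto_unbox = FALSE)
  invisible(manifest)
}
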