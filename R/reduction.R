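#' Per-pixel q and azimuth map of a detector frame
#'
#' For each pixel, the radial distance r from the beam center gives the
#' scattering angle 2 theta = atan(r / sdd) and thence
#' q = 4 pi sin(theta) / lambda. The azimuth is measured from the horizontal
#' equator (degrees, counter-clockwise in detector view with row 1 at the
#' top), reported both over the full circle [0, 360) and folded to the
#' angular distance from the equator in [0, 90] (fiber patterns are
#' 180-degree periodic). A cos^3(2 theta) solid-angle weight for flat
#' detectors is included.
#'
#' @param geometry a [Geometry-class].
#' @param shape frame shape (rows, cols).
#' @return list of matrices \code{q} (1/A), \code{azimuth} (degrees,
#'   [0, 360)), \code{equatorDist} (degrees, [0, 90]), \code{solidAngle}
#'   (relative cos^3(2 theta) weight), plus \code{twoTheta} (radians).
#' @examples
#' g <- Geometry(6.0, 8000, c(64.5, 64.5), 7.5)
#' qm <- buildQMap(g, c(128, 128))
#' range(qm$q)
#' @export
buildQMap <- function(geometry, shape) {
  validObject(geometry)
  nr <- shape[1]; nc <- shape[2]
  row <- matrix(seq_len(nr), nr, nc)
  col <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # x to the right, y upward (row index grows downward)
  x <- (col - geometry@beamCenter[2]) * geometry@pixelSize
  y <- (geometry@beamCenter[1] - row) * geometry@pixelSize
  r <- sqrt(x^2 + y^2)
  twoTheta <- atan(r / geometry@sdd)
  q <- 4 * pi * sin(twoTheta / 2) / geometry@wavelength
  az <- (atan2(y, x) * 180 / pi) %% 360
  fold <- az %% 180                       # [0, 180)
  eqd <- pmin(fold, 180 - fold)           # distance from horizontal, [0, 90]
  list(q = q, azimuth = az, equatorDist = eqd,
       solidAngle = cos(twoTheta)^3, twoTheta = twoTheta)
}

# folded angular distance from the equator defined by a SectorSpec
.equatorDistance <- function(qmap, sectors) {
  d <- (qmap$azimuth - sectors@equatorAzimuth) %% 180
  pmin(d, 180 - d)
}

# default log-spaced q-bin edges covering the unmasked frame
.defaultQBins <- function(qv, binsPerDecade = 40L) {
  qv <- qv[qv > 0]
  lo <- stats::quantile(qv, 0.002); hi <- max(qv)
  n <- max(2L, ceiling(log10(hi / lo) * binsPerDecade))
  10^seq(log10(lo), log10(hi), length.out = n + 1L)
}

# per-pixel solid-angle-corrected intensity and Poisson variance
.pixelIntensity <- function(frame, qmap) {
  sc <- frame@exposure * qmap$solidAngle
  list(I = frame@counts / sc, var = pmax(frame@counts, 1) / sc^2)
}

#' Azimuthal intensity profile in a q annulus
#'
#' Mean solid-angle-corrected counts per azimuth bin for unmasked pixels
#' with q in [q_lo, q_hi), with propagated Poisson uncertainties. Azimuth
#' bins with no pixels are flagged as gaps (NA intensity, \code{gap = TRUE}),
#' never silently set to zero.
#'
#' @param frame a [DetectorFrame-class].
#' @param qBin numeric pair (q_lo, q_hi) in 1/A.
#' @param nAzimuth number of azimuth bins over [0, 360).
#' @return data.frame with columns azimuth (bin center, degrees), I, sigma,
#'   n (pixel count), gap (logical).
#' @export
azimuthalProfile <- function(frame, qBin, nAzimuth = 72L) {
  validObject(frame)
  qmap <- buildQMap(frame@geometry, dim(frame@counts))
  if (qBin[1] >= qBin[2]) stop("qBin must be increasing")
  cov <- range(qmap$q[!frame@mask])
  if (qBin[2] < cov[1] || qBin[1] > cov[2])
    stop("qBin outside the frame's q coverage [",
         signif(cov[1], 3), ", ", signif(cov[2], 3), "]")
  sel <- !frame@mask & qmap$q >= qBin[1] & qmap$q < qBin[2]
  px <- .pixelIntensity(frame, qmap)
  edges <- seq(0, 360, length.out = nAzimuth + 1L)
  idx <- findInterval(qmap$azimuth[sel], edges, rightmost.closed = TRUE)
  n <- tabulate(idx, nAzimuth)
  Isum <- rowsum(px$I[sel], idx, reorder = FALSE)
  Vsum <- rowsum(px$var[sel], idx, reorder = FALSE)
  I <- rep(NA_real_, nAzimuth); V <- rep(NA_real_, nAzimuth)
  present <- sort(unique(idx))
  I[present] <- Isum[as.character(present), 1] / n[present]
  V[present] <- Vsum[as.character(present), 1] / n[present]^2
  data.frame(azimuth = (edges[-1] + edges[-length(edges)]) / 2,
             I = I, sigma = sqrt(V), n = n, gap = n == 0L)
}

#' Separate the equatorial anisotropic component of a frame
#'
#' For each q bin, the isotropic level is estimated as the mean
#' solid-angle-corrected intensity in a reference azimuth band far from the
#' equator, and subtracted from the mean intensity in the equatorial band.
#' Negative values are retained (they are noise around zero, and clipping
#' would bias the profile). Uncertainties combine in quadrature. q bins in
#' which either band has no unmasked pixels are dropped; the number of
#' dropped bins is recorded in the profile metadata.
#'
#' @param frame a [DetectorFrame-class].
#' @param sectors a [SectorSpec-class].
#' @param qBins optional vector of q-bin edges (1/A); default 40 log-spaced
#'   bins per decade over the frame's coverage.
#' @param binsPerDecade bins per decade for the default grid.
#' @return a [Profile1D-class] of the anisotropic equatorial intensity
#'   (relative units); \code{meta$droppedBins} counts discarded q bins.
#' @export
separateAnisotropic <- function(frame, sectors = SectorSpec(),
                                qBins = NULL, binsPerDecade = 40L) {
  validObject(frame); validObject(sectors)
  qmap <- buildQMap(frame@geometry, dim(frame@counts))
  eqd <- .equatorDistance(qmap, sectors)
  ok <- !frame@mask & qmap$q > 0
  if (is.null(qBins)) qBins <- .defaultQBins(qmap$q[ok], binsPerDecade)
  px <- .pixelIntensity(frame, qmap)

  inEq  <- ok & eqd <= sectors@halfWidthEquator
  inRef <- ok & eqd >= sectors@referenceBand[1] &
                eqd <= sectors@referenceBand[2]

  bandStats <- function(sel) {
    idx <- findInterval(qmap$q[sel], qBins, rightmost.closed = TRUE)
    keep <- idx >= 1L & idx <= length(qBins) - 1L
    idx <- idx[keep]
    n <- tabulate(idx, length(qBins) - 1L)
    I <- rep(NA_real_, length(n)); V <- rep(NA_real_, length(n))
    qm <- rep(NA_real_, length(n))
    if (length(idx)) {
      Is <- rowsum(px$I[sel][keep], idx, reorder = FALSE)
      Vs <- rowsum(px$var[sel][keep], idx, reorder = FALSE)
      Qs <- rowsum(qmap$q[sel][keep], idx, reorder = FALSE)
      present <- as.integer(rownames(Is))
      I[present] <- Is[, 1] / n[present]
      V[present] <- Vs[, 1] / n[present]^2
      qm[present] <- Qs[, 1] / n[present]
    }
    list(I = I, V = V, n = n, q = qm)
  }
  eq <- bandStats(inEq)
  rf <- bandStats(inRef)
  # bin q = mean pixel q of the equator band (the band being reported);
  # on steep profiles this is far less biased than the bin center
  qc <- eq$q
  good <- eq$n > 0L & rf$n > 0L
  dropped <- sum(!good)
  Profile1D(q = qc[good],
            I = eq$I[good] - rf$I[good],
            sigma = sqrt(eq$V[good] + rf$V[good]),
            meta = list(sectors = sectors, droppedBins = dropped,
                        sdd = frame@geometry@sdd))
}

#' Merge 1D profiles from several detector configurations
#'
#' Each profile is rescaled onto the reference by a least-squares scalar
#' factor determined in the q-overlap with the already-merged set (profiles
#' are processed outward from the reference in order of median q), then all
#' points are concatenated, sorted and log-rebinned.
#'
#' @param profiles list of [Profile1D-class].
#' @param scaleReference index of the profile whose scale is kept (default:
#'   the one with the lowest median q, i.e. the longest camera length).
#' @param binsPerDecade rebinning density (default 40).
#' @return merged [Profile1D-class]; \code{meta$scaleFactors} records the
#'   per-profile factors and \code{meta$merged} the number of configurations.
#' @export
mergeProfiles <- function(profiles, scaleReference = NULL,
                          binsPerDecade = 40L) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, is, TRUE, class2 = "Profile1D")))
  if (length(profiles) == 1L) {
    out <- rebinLog(profiles[[1L]], binsPerDecade)
    out@meta$scaleFactors <- 1
    out@meta$merged <- 1L
    return(out)
  }
  med <- vapply(profiles, function(p) stats::median(p@q), 0)
  if (is.null(scaleReference)) scaleReference <- which.min(med)
  ord <- order(abs(rank(med) - rank(med)[scaleReference]))
  scale <- rep(NA_real_, length(profiles))
  scale[scaleReference] <- 1
  mq <- profiles[[scaleReference]]@q
  mI <- profiles[[scaleReference]]@I
  ms <- profiles[[scaleReference]]@sigma
  for (i in ord[-1L]) {
    p <- profiles[[i]]
    lo <- max(min(p@q), min(mq)); hi <- min(max(p@q), max(mq))
    if (lo >= hi)
      stop("no q overlap between profile ", i,
           " and the merged set: gap between ", signif(min(p@q, mq), 3),
           " and ", signif(max(p@q, mq), 3))
    insideP <- p@q >= lo & p@q <= hi
    refI <- stats::approx(mq, mI, xout = p@q[insideP], rule = 1)$y
    w <- 1 / pmax(p@sigma[insideP]^2, 1e-300)
    okp <- is.finite(refI)
    # least squares: minimise sum w (refI - c * I_p)^2
    denom <- sum(w[okp] * p@I[insideP][okp]^2)
    if (denom <= 0) stop("degenerate overlap with profile ", i)
    scale[i] <- sum(w[okp] * refI[okp] * p@I[insideP][okp]) / denom
    mq <- c(mq, p@q); mI <- c(mI, scale[i] * p@I)
    ms <- c(ms, scale[i] * p@sigma)
    o <- order(mq); mq <- mq[o]; mI <- mI[o]; ms <- ms[o]
  }
  # strictly increasing q for the container: merge exact duplicates
  merged <- Profile1D(q = mq + cumsum(c(0, diff(mq) == 0)) * 1e-12,
                      I = mI, sigma = ms)
  out <- rebinLog(merged, binsPerDecade)
  out@meta$scaleFactors <- scale
  out@meta$merged <- length(profiles)
  out
}

#' Rebin a profile on a logarithmic q grid
#'
#' Inverse-variance-weighted mean of I (and of q) per log-spaced bin; empty
#' bins are dropped. Points with sigma = 0 are combined unweighted within
#' their bin.
#'
#' @param profile a [Profile1D-class].
#' @param binsPerDecade number of bins per decade of q (>= 1).
#' @return rebinned [Profile1D-class]. If the requested bin density exceeds
#'   the point density everywhere, the input is returned unchanged.
#' @export
rebinLog <- function(profile, binsPerDecade = 40L) {
  validObject(profile)
  stopifnot(binsPerDecade >= 1)
  q <- profile@q
  if (length(q) < 2L) return(profile)
  n <- ceiling(log10(max(q) / min(q)) * binsPerDecade)
  if (n < 1L) n <- 1L
  edges <- 10^seq(log10(min(q)), log10(max(q)), length.out = n + 1L)
  idx <- findInterval(q, edges, rightmost.closed = TRUE)
  if (max(tabulate(idx)) <= 1L) return(profile)   # nothing to combine
  w <- ifelse(profile@sigma > 0, 1 / profile@sigma^2, NA_real_)
  out <- lapply(split(seq_along(q), idx), function(ii) {
    wi <- w[ii]
    if (anyNA(wi)) wi <- rep(1, length(ii))       # unweighted fallback
    c(q = sum(wi * q[ii]) / sum(wi),
      I = sum(wi * profile@I[ii]) / sum(wi),
      sigma = if (anyNA(w[ii])) 0 else sqrt(1 / sum(wi)))
  })
  m <- do.call(rbind, out)
  Profile1D(q = m[, "q"], I = m[, "I"], sigma = m[, "sigma"],
            absolute = profile@absolute, meta = profile@meta)
}

#' Read / write 3-column scattering profiles
#'
#' Plain-text exchange format: `#`-prefixed metadata header lines followed
#' by whitespace-separated columns q, I, sigma. The reader tolerates
#' comment and blank lines anywhere.
#'
#' @param profile a [Profile1D-class].
#' @param path file path.
#' @param header named character vector written as additional `# key: value`
#'   lines.
#' @return \code{writeProfile}: the path, invisibly. \code{readProfile}:
#'   a [Profile1D-class].
#' @export
writeProfile <- function(profile, path, header = character()) {
  validObject(profile)
  lines <- c(
    "# fibrilSANS 1D profile",
    sprintf("# units: q 1/Angstrom, I %s",
            if (profile@absolute) "1/cm (absolute)" else "relative"),
    if (length(header)) sprintf("# %s: %s", names(header), header),
    "# q I sigma",
    sprintf("%.8e %.8e %.8e", profile@q, profile@I, profile@sigma))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  m <- do.call(rbind, lapply(strsplit(trimws(lines[keep]), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  absolute <- any(grepl("absolute", lines[!keep], fixed = TRUE))
  Profile1D(q = m[, 1], I = m[, 2],
            sigma = ifelse(is.na(m[, 3]), 0, m[, 3]),
            absolute = absolute, meta = list(source = path))
}

#' Read / write detector frames as text with a YAML geometry sidecar
#'
#' The counts matrix is written as a whitespace-separated integer matrix,
#' the geometry (wavelength, sdd, beam center, pixel size, exposure) as a
#' YAML sidecar next to it, and the mask (if any pixel is masked) as a 0/1
#' matrix.
#'
#' @param frame a [DetectorFrame-class].
#' @param path path of the counts file; the sidecar is `<path>.geom.yaml`
#'   and the mask `<path>.mask.txt`.
#' @return \code{writeFrame}: character vector of files written, invisibly.
#'   \code{readFrame}: a [DetectorFrame-class].
#' @export
writeFrame <- function(frame, path) {
  validObject(frame)
  utils::write.table(frame@counts, path, row.names = FALSE,
                     col.names = FALSE)
  g <- frame@geometry
  side <- paste0(path, ".geom.yaml")
  yaml::write_yaml(list(wavelength = g@wavelength, sdd = g@sdd,
                        beam_center = as.numeric(g@beamCenter),
                        pixel_size = g@pixelSize,
                        exposure = frame@exposure), side)
  files <- c(path, side)
  if (any(frame@mask)) {
    mfile <- paste0(path, ".mask.txt")
    utils::write.table(frame@mask * 1L, mfile, row.names = FALSE,
                       col.names = FALSE)
    files <- c(files, mfile)
  }
  invisible(files)
}

#' @rdname writeFrame
#' @export
readFrame <- function(path) {
  counts <- as.matrix(utils::read.table(path))
  dimnames(counts) <- NULL
  side <- yaml::read_yaml(paste0(path, ".geom.yaml"))
  g <- Geometry(side$wavelength, side$sdd, unlist(side$beam_center),
                side$pixel_size)
  mfile <- paste0(path, ".mask.txt")
  mask <- if (file.exists(mfile)) {
    m <- as.matrix(utils::read.table(mfile)) > 0
    dimnames(m) <- NULL
    m
  } else NULL
  DetectorFrame(counts, g, exposure = side$exposure, mask = mask)
}
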