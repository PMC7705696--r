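#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## Materials and scattering-length densities
## ---------------------------------------------------------------------------

#' Material composition for scattering-length-density calculations
#'
#' A material is described by its stoichiometric formula (element or isotope
#' symbols mapped to non-negative counts per formula unit), its mass density,
#' and the number of labile (exchangeable) hydrogens per formula unit, which
#' controls how the composition responds to a deuterated solvent.
#'
#' @slot name character label.
#' @slot formula named numeric vector of stoichiometric counts, e.g.
#'   \code{c(C = 6, H = 10, O = 5)}. Deuterium is the symbol \code{"D"}.
#' @slot massDensity mass density in g/cm^3 (> 0).
#' @slot nExchangeableH number of labile hydrogens per formula unit
#'   (0 <= n <= H count).
#'
#' @seealso [Material()], [computeSLD()], [materialPreset()]
#' @export
setClass("Material",
  representation(
    name          = "character",
    formula       = "numeric",
    massDensity   = "numeric",
    nExchangeableH = "numeric"
  ),
  prototype(nExchangeableH = 0)
)

setValidity("Material", function(object) {
  msg <- character()
  f <- object@formula
  if (length(f) == 0L) msg <- c(msg, "formula must be non-empty")
  if (is.null(names(f)) || any(!nzchar(names(f))))
    msg <- c(msg, "formula must be a named vector of element symbols")
  if (any(!is.finite(f)) || any(f < 0))
    msg <- c(msg, "stoichiometric counts must be finite and >= 0")
  if (length(object@massDensity) != 1L || !is.finite(object@massDensity) ||
      object@massDensity <= 0)
    msg <- c(msg, "massDensity must be a single positive number")
  nH <- sum(f[names(f) == "H"])
  if (length(object@nExchangeableH) != 1L || object@nExchangeableH < 0 ||
      object@nExchangeableH > nH + 1e-9)
    msg <- c(msg, "nExchangeableH must lie in [0, H count]")
  if (length(msg)) msg else TRUE
})

#' Construct a Material
#'
#' @param name character label.
#' @param formula named numeric vector of stoichiometric counts.
#' @param massDensity mass density in g/cm^3.
#' @param nExchangeableH labile hydrogens per formula unit (default 0).
#' @return a [Material-class] object.
#' @examples
#' Material("D2O", c(D = 2, O = 1), massDensity = 1.105)
#' @export
Material <- function(name, formula, massDensity, nExchangeableH = 0) {
  new("Material", name = as.character(name)[1L],
      formula = formula, massDensity = as.numeric(massDensity),
      nExchangeableH = as.numeric(nExchangeableH))
}

#' Neutron scattering-length density
#'
#' Holds a coherent scattering-length density rho in 1/Angstrom^2 together
#' with an optional per-element breakdown of the summed scattering length.
#'
#' @slot rho scattering-length density in 1/A^2.
#' @slot components named numeric vector: per-element contribution to the
#'   summed coherent scattering length (fm), or NULL.
#' @slot material name of the originating material.
#' @export
setClass("SLDValue",
  representation(rho = "numeric", components = "numericOrNULL",
                 material = "character"),
  prototype(components = NULL, material = NA_character_)
)

setValidity("SLDValue", function(object) {
  if (length(object@rho) != 1L || !is.finite(object@rho))
    "rho must be a single finite number" else TRUE
})

## ---------------------------------------------------------------------------
## Detector geometry, frames and 1D profiles
## ---------------------------------------------------------------------------

#' Detector geometry for a small-angle scattering frame
#'
#' The convention throughout is a vertically mounted fiber axis, so the
#' equatorial streak is horizontal on the detector. Pixel (row, col) indices
#' are 1-based; rows run vertically, columns horizontally.
#'
#' @slot wavelength neutron wavelength in Angstrom (> 0).
#' @slot sdd sample-to-detector distance in mm (> 0).
#' @slot beamCenter length-2 numeric (row, col) of the direct beam, pixels.
#' @slot pixelSize pixel edge length in mm (square pixels).
#' @export
setClass("Geometry",
  representation(wavelength = "numeric", sdd = "numeric",
                 beamCenter = "numeric", pixelSize = "numeric")
)

setValidity("Geometry", function(object) {
  msg <- character()
  for (s in c("wavelength", "sdd", "pixelSize")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (length(object@beamCenter) != 2L || any(!is.finite(object@beamCenter)))
    msg <- c(msg, "beamCenter must be a finite (row, col) pair")
  if (length(msg)) msg else TRUE
})

#' @param wavelength neutron wavelength, Angstrom.
#' @param sdd sample-to-detector distance, mm.
#' @param beamCenter (row, col) beam-center position, pixels.
#' @param pixelSize pixel size, mm.
#' @rdname Geometry-class
#' @export
Geometry <- function(wavelength, sdd, beamCenter, pixelSize) {
  new("Geometry", wavelength = wavelength, sdd = sdd,
      beamCenter = as.numeric(beamCenter), pixelSize = pixelSize)
}

#' A 2D detector frame with counts, geometry and mask
#'
#' @slot counts non-negative count matrix.
#' @slot exposure exposure time, s.
#' @slot geometry a [Geometry-class].
#' @slot mask logical matrix, same shape as counts; TRUE = exclude pixel.
#' @export
setClass("DetectorFrame",
  representation(counts = "matrix", exposure = "numeric",
                 geometry = "Geometry", mask = "matrix")
)

setValidity("DetectorFrame", function(object) {
  msg <- character()
  if (any(object@counts < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  if (!identical(dim(object@counts), dim(object@mask)))
    msg <- c(msg, "mask must have the same shape as counts")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (length(object@exposure) != 1L || object@exposure <= 0)
    msg <- c(msg, "exposure must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param counts count matrix.
#' @param geometry a [Geometry-class].
#' @param exposure exposure time in seconds.
#' @param mask logical exclusion mask (default: nothing masked).
#' @rdname DetectorFrame-class
#' @export
DetectorFrame <- function(counts, geometry, exposure = 1,
                          mask = NULL) {
  counts <- as.matrix(counts)
  if (is.null(mask))
    mask <- matrix(FALSE, nrow(counts), ncol(counts))
  new("DetectorFrame", counts = counts, exposure = exposure,
      geometry = geometry, mask = mask)
}

#' A 1D scattering profile (q, I, sigma)
#'
#' @slot q scattering-vector magnitudes in 1/Angstrom, strictly increasing,
#'   all > 0.
#' @slot I intensities (relative units unless \code{absolute}).
#' @slot sigma one-standard-deviation uncertainties, same units as I, >= 0.
#' @slot absolute logical; TRUE if I is in absolute units (1/cm).
#' @slot meta provenance list (sectors, merged configurations, scale factors,
#'   generator truth, ...).
#' @export
setClass("Profile1D",
  representation(q = "numeric", I = "numeric", sigma = "numeric",
                 absolute = "logical", meta = "list"),
  prototype(absolute = FALSE, meta = list())
)

setValidity("Profile1D", function(object) {
  msg <- character()
  n <- length(object@q)
  if (length(object@I) != n || length(object@sigma) != n)
    msg <- c(msg, "q, I and sigma must have equal length")
  if (n && any(object@q <= 0))
    msg <- c(msg, "q must be > 0")
  if (n && any(diff(object@q) <= 0))
    msg <- c(msg, "q must be strictly increasing")
  if (n && any(object@sigma < 0))
    msg <- c(msg, "sigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param q scattering vector, 1/A, strictly increasing.
#' @param I intensity.
#' @param sigma uncertainty (default 0).
#' @param absolute logical, absolute-unit flag.
#' @param meta provenance list.
#' @rdname Profile1D-class
#' @export
Profile1D <- function(q, I, sigma = rep(0, length(q)), absolute = FALSE,
                      meta = list()) {
  o <- order(q)
  new("Profile1D", q = as.numeric(q[o]), I = as.numeric(I[o]),
      sigma = as.numeric(sigma[o]), absolute = absolute, meta = meta)
}

#' Azimuthal sector specification for equatorial separation
#'
#' Azimuth is measured in degrees from the equator (the horizontal direction
#' for a vertical fiber axis) and folded into [0, 90] by the 180-degree
#' periodicity of fiber diffraction, so a single band covers all four
#' symmetric sectors.
#'
#' @slot equatorAzimuth detector azimuth of the equator, degrees
#'   (0 = horizontal; 90 would treat the meridian as "equator").
#' @slot halfWidthEquator half-width of the equatorial band, degrees,
#'   0 < w < 90.
#' @slot referenceBand length-2 numeric; folded angular distance from the
#'   equator (degrees) delimiting the band used to estimate the isotropic
#'   component. Must be disjoint from the equator band.
#' @export
setClass("SectorSpec",
  representation(equatorAzimuth = "numeric", halfWidthEquator = "numeric",
                 referenceBand = "numeric"),
  prototype(equatorAzimuth = 0, halfWidthEquator = 15,
            referenceBand = c(60, 90))
)

setValidity("SectorSpec", function(object) {
  msg <- character()
  w <- object@halfWidthEquator
  if (length(w) != 1L || w <= 0 || w >= 90)
    msg <- c(msg, "halfWidthEquator must lie in (0, 90)")
  rb <- object@referenceBand
  if (length(rb) != 2L || rb[1] >= rb[2] || rb[1] < 0 || rb[2] > 90)
    msg <- c(msg, "referenceBand must be an increasing pair within [0, 90]")
  if (length(rb) == 2L && length(w) == 1L && rb[1] <= w)
    msg <- c(msg, "referenceBand must be disjoint from the equator band")
  if (length(msg)) msg else TRUE
})

#' @param equatorAzimuth equator azimuth, degrees.
#' @param halfWidthEquator equator-band half-width, degrees.
#' @param referenceBand folded distance-from-equator range, degrees.
#' @rdname SectorSpec-class
#' @export
SectorSpec <- function(equatorAzimuth = 0, halfWidthEquator = 15,
                       referenceBand = c(60, 90)) {
  new("SectorSpec", equatorAzimuth = equatorAzimuth,
      halfWidthEquator = halfWidthEquator,
      referenceBand = as.numeric(referenceBand))
}

## ---------------------------------------------------------------------------
## Scattering model parameters and derived structure
## ---------------------------------------------------------------------------

#' Parameters of the three-term equatorial wood scattering model
#'
#' The equatorial intensity is modelled as
#' \deqn{I(q) = A_{mf} \langle\Phi^2(qR)\rangle S_N(q) + A_b
#'   e^{-q^2/(2\sigma_b^2)} + B q^{-\alpha} + C,}
#' a paracrystalline stack of polydisperse cylindrical microfibrils, a
#' Gaussian bundle term centered at q = 0, a power law from large pores and
#' lumina, and a flat background.
#'
#' All lengths are Angstrom, q-widths 1/Angstrom. The hexagonal interplanar
#' spacing d100 = (sqrt(3)/2) * aCC is always derived, never stored.
#'
#' @slot A_mf microfibril amplitude (>= 0).
#' @slot R_mean mean cylinder radius, A (> 0).
#' @slot R_sd radius standard deviation, A (>= 0).
#' @slot aCC center-to-center distance between neighboring microfibrils, A.
#' @slot g paracrystalline distortion: displacement sd as a fraction of d100,
#'   0 <= g < 0.5.
#' @slot N coherently ordered lattice planes (integer >= 1).
#' @slot A_b bundle Gaussian amplitude (>= 0).
#' @slot sigma_b bundle Gaussian width, 1/A (> 0).
#' @slot B_pl power-law prefactor (>= 0).
#' @slot alpha power-law exponent, in [3, 4].
#' @slot C_bg constant background (>= 0).
#' @export
setClass("WoodModelParams",
  representation(A_mf = "numeric", R_mean = "numeric", R_sd = "numeric",
                 aCC = "numeric", g = "numeric", N = "numeric",
                 A_b = "numeric", sigma_b = "numeric",
                 B_pl = "numeric", alpha = "numeric", C_bg = "numeric")
)

setValidity("WoodModelParams", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(object@A_mf >= 0, "A_mf must be >= 0")
  chk(object@R_mean > 0, "R_mean must be > 0")
  chk(object@R_sd >= 0, "R_sd must be >= 0")
  chk(object@aCC > 0, "aCC must be > 0")
  chk(object@g >= 0 && object@g < 0.5, "g must lie in [0, 0.5)")
  chk(object@N >= 1 && abs(object@N - round(object@N)) < 1e-8,
      "N must be an integer >= 1")
  chk(object@A_b >= 0, "A_b must be >= 0")
  chk(object@sigma_b > 0, "sigma_b must be > 0")
  chk(object@B_pl >= 0, "B_pl must be >= 0")
  chk(object@alpha >= 3 && object@alpha <= 4, "alpha must lie in [3, 4]")
  chk(object@C_bg >= 0, "C_bg must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct wood model parameters
#'
#' Defaults correspond to native softwood in heavy water: 1.2 nm radius
#' microfibrils, 4.3 nm center-to-center spacing, bundle Gaussian width
#' giving an 18.5 nm bundle diameter, Porod exponent 4.
#'
#' @param A_mf,R_mean,R_sd,aCC,g,N,A_b,sigma_b,B_pl,alpha,C_bg see
#'   [WoodModelParams-class].
#' @return a validated [WoodModelParams-class] object.
#' @examples
#' p <- WoodModelParams(aCC = 43, sigma_b = 2 * sqrt(2) / 185)
#' d100(p)
#' @export
WoodModelParams <- function(A_mf = 0.012, R_mean = 12, R_sd = 2,
                            aCC = 43, g = 0.2, N = 4,
                            A_b = 1, sigma_b = 2 * sqrt(2) / 185,
                            B_pl = 1e-9, alpha = 4, C_bg = 1e-3) {
  new("WoodModelParams", A_mf = A_mf, R_mean = R_mean, R_sd = R_sd,
      aCC = aCC, g = g, N = N, A_b = A_b, sigma_b = sigma_b,
      B_pl = B_pl, alpha = alpha, C_bg = C_bg)
}

#' Structural quantities derived from a fitted model
#'
#' @slot bundleDiameter microfibril-bundle diameter, nm.
#' @slot interfibrillarDistance center-to-center microfibril spacing, nm.
#' @slot peakQ position of the microfibril packing peak, 1/A.
#' @export
setClass("DerivedStructure",
  representation(bundleDiameter = "numeric",
                 interfibrillarDistance = "numeric",
                 peakQ = "numeric")
)

## ---------------------------------------------------------------------------
## Fitting
## ---------------------------------------------------------------------------

#' Configuration for equatorial model fitting
#'
#' @slot qRange fit window (q_lo, q_hi) in 1/A.
#' @slot lower,upper named numeric vectors of box bounds for the shape
#'   parameters (R_mean, R_sd, aCC, g, sigma_b, alpha).
#' @slot frozen named list of parameters held fixed (not fitted).
#' @slot nStarts number of multistart optimisations.
#' @slot loss "linear" (weighted least squares on I) or "log"
#'   (on log I, for profiles spanning many decades).
#' @slot seed integer RNG seed; fits are bit-reproducible given the seed.
#' @export
setClass("FitConfig",
  representation(qRange = "numeric", lower = "numeric", upper = "numeric",
                 frozen = "list", nStarts = "numeric", loss = "character",
                 seed = "numeric")
)

setValidity("FitConfig", function(object) {
  msg <- character()
  if (length(object@qRange) != 2L || object@qRange[1] >= object@qRange[2] ||
      object@qRange[1] <= 0)
    msg <- c(msg, "qRange must be an increasing positive pair")
  if (!object@loss %in% c("linear", "log"))
    msg <- c(msg, 'loss must be "linear" or "log"')
  if (object@nStarts < 1) msg <- c(msg, "nStarts must be >= 1")
  bad <- names(object@lower)[object@lower > object@upper[names(object@lower)]]
  if (length(bad)) msg <- c(msg, paste("lower > upper for:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a fit configuration
#'
#' Default bounds reflect the physical regime of packed cellulose
#' microfibrils: radii 8-20 A (2-3 nm thick fibrils), spacing 25-60 A, bundle
#' Gaussian width 0.005-0.05 1/A. The Porod exponent alpha and the number of
#' coherent planes N are frozen by default (alpha = 4, N = 4).
#'
#' @param qRange fit window in 1/A, default c(0.002, 0.3).
#' @param lower,upper named bound overrides for shape parameters.
#' @param frozen named list of frozen parameter values; entries here are not
#'   fitted. Use \code{frozen = list(alpha = NULL)} semantics by simply
#'   omitting a default-frozen name from the list to free it.
#' @param nStarts multistart count, default 16.
#' @param loss "linear" or "log".
#' @param seed integer seed.
#' @return a [FitConfig-class].
#' @export
FitConfig <- function(qRange = c(0.002, 0.3),
                      lower = NULL, upper = NULL,
                      frozen = list(alpha = 4, N = 4),
                      nStarts = 16, loss = "linear", seed = 1L) {
  lo <- c(A_mf = 0, R_mean = 8,  R_sd = 0, aCC = 25, g = 0.01,
          A_b = 0, sigma_b = 0.005, B_pl = 0, alpha = 3, C_bg = 0, N = 1)
  hi <- c(A_mf = Inf, R_mean = 20, R_sd = 5, aCC = 60, g = 0.45,
          A_b = Inf, sigma_b = 0.05, B_pl = Inf, alpha = 4, C_bg = Inf, N = 12)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  new("FitConfig", qRange = as.numeric(qRange), lower = lo, upper = hi,
      frozen = frozen, nStarts = nStarts, loss = loss, seed = as.numeric(seed))
}

#' Result of an equatorial model fit
#'
#' @slot params fitted [WoodModelParams-class].
#' @slot stderr named numeric vector of standard errors for free parameters.
#' @slot chi2Reduced reduced chi-squared of the best fit.
#' @slot derived [DerivedStructure-class], recomputed from params.
#' @slot perTerm data.frame of per-term model curves on the fitted q grid.
#' @slot convergence list: status message, n function evaluations, index of
#'   the winning start, per-start objective values, names of parameters that
#'   ended on a bound.
#' @slot data the fitted [Profile1D-class] restricted to the fit window.
#' @export
setClass("FitResult",
  representation(params = "WoodModelParams", stderr = "numeric",
                 chi2Reduced = "numeric", derived = "DerivedStructure",
                 perTerm = "data.frame", convergence = "list",
                 data = "Profile1D")
)

setValidity("FitResult", function(object) {
  if (length(object@chi2Reduced) == 1L && is.finite(object@chi2Reduced) &&
      object@chi2Reduced < 0) "chi2Reduced must be >= 0" else TRUE
})

#' Result of a polymer-solution size fit
#'
#' @slot Rg radius of gyration, Angstrom.
#' @slot RgStderr standard error of Rg, Angstrom.
#' @slot I0 forward intensity.
#' @slot background fitted flat background.
#' @slot method "guinier" or "debye".
#' @slot fitWindow q-window actually used, 1/A.
#' @export
setClass("PolymerSolutionFit",
  representation(Rg = "numeric", RgStderr = "numeric", I0 = "numeric",
                 background = "numeric", method = "character",
                 fitWindow = "numeric")
)

setValidity("PolymerSolutionFit", function(object) {
  msg <- character()
  if (object@Rg <= 0) msg <- c(msg, "Rg must be > 0")
  if (!object@method %in% c("guinier", "debye"))
    msg <- c(msg, 'method must be "guinier" or "debye"')
  if (object@method == "guinier" &&
      object@fitWindow[2] * object@Rg > 1.3 + 1e-6)
    msg <- c(msg, "guinier fits must satisfy q_max * Rg <= 1.3")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Synthetic data
## ---------------------------------------------------------------------------

#' Specification for synthetic multi-distance SANS frames
#'
#' Emulates a pinhole SANS measurement of a vertically mounted wood section:
#' an equatorially concentrated anisotropic signal (microfibril packing peak,
#' bundle Gaussian, oriented power law) smeared by a wrapped-Gaussian
#' orientation distribution, over an isotropic background, with Poisson
#' counting noise, recorded at several sample-to-detector distances.
#'
#' @slot truth ground-truth [WoodModelParams-class].
#' @slot orientationSpread azimuthal smearing sd about the equator, degrees,
#'   in (0, 45).
#' @slot isoFlat flat isotropic background level (model intensity units).
#' @slot isoPorod isotropic q^-4 prefactor (0 disables).
#' @slot geometries list of [Geometry-class], one per detector distance.
#' @slot frameShape (rows, cols) of each frame.
#' @slot exposure exposure time per frame, s.
#' @slot countsScale expected counts per pixel per unit model intensity at
#'   normal incidence (> 0).
#' @slot seed integer master seed; per-frame child seeds derive from it.
#' @export
setClass("SyntheticSpec",
  representation(truth = "WoodModelParams", orientationSpread = "numeric",
                 isoFlat = "numeric", isoPorod = "numeric",
                 geometries = "list", frameShape = "numeric",
                 exposure = "numeric", countsScale = "numeric",
                 seed = "numeric")
)

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@orientationSpread <= 0 || object@orientationSpread >= 45)
    msg <- c(msg, "orientationSpread must lie in (0, 45) degrees")
  if (object@countsScale <= 0) msg <- c(msg, "countsScale must be > 0")
  if (length(object@geometries) < 1L)
    msg <- c(msg, "at least one geometry is required")
  if (!all(vapply(object@geometries, is, TRUE, class2 = "Geometry")))
    msg <- c(msg, "geometries must be a list of Geometry objects")
  if (length(msg)) msg else TRUE
})

#' Default D11-like detector geometries
#'
#' Three configurations at 6.0 A wavelength with sample-to-detector distances
#' of 1.5 m, 8 m and 39 m, jointly covering q = 0.002-0.3 1/A on a
#' 128 x 128 frame with 7.5 mm pixels.
#'
#' @param wavelength wavelength in Angstrom.
#' @param sdd numeric vector of sample-detector distances in mm.
#' @param frameShape (rows, cols); beam center defaults to the frame center.
#' @param pixelSize pixel size in mm.
#' @return list of [Geometry-class].
#' @export
defaultGeometries <- function(wavelength = 6.0,
                              sdd = c(1500, 8000, 39000),
                              frameShape = c(128L, 128L),
                              pixelSize = 7.5) {
  bc <- (frameShape + 1) / 2
  lapply(sdd, function(d)
    Geometry(wavelength = wavelength, sdd = d, beamCenter = bc,
             pixelSize = pixelSize))
}

#' @param truth ground-truth [WoodModelParams-class].
#' @param orientationSpread azimuthal smearing sd, degrees.
#' @param isoFlat flat isotropic level.
#' @param isoPorod isotropic q^-4 prefactor.
#' @param geometries list of [Geometry-class].
#' @param frameShape frame shape (rows, cols).
#' @param exposure exposure per frame, s.
#' @param countsScale expected counts per unit intensity.
#' @param seed integer master seed.
#' @rdname SyntheticSpec-class
#' @export
SyntheticSpec <- function(truth = WoodModelParams(),
                          orientationSpread = 10,
                          isoFlat = 5e-3, isoPorod = 0,
                          geometries = defaultGeometries(),
                          frameShape = c(128L, 128L),
                          exposure = 1, countsScale = 2000,
                          seed = 1L) {
  new("SyntheticSpec", truth = truth, orientationSpread = orientationSpread,
      isoFlat = isoFlat, isoPorod = isoPorod, geometries = geometries,
      frameShape = as.numeric(frameShape), exposure = exposure,
      countsScale = countsScale, seed = as.numeric(seed))
}
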