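#' Accessors for fibrilSANS objects
#'
#' Small accessor generics used across the package: \code{qValues},
#' \code{intensity} and \code{intensitySigma} extract the columns of a
#' [Profile1D-class]; \code{fittedParams}, \code{derivedStructure} and
#' \code{perTermProfiles} extract the parts of a [FitResult-class];
#' \code{d100} gives the hexagonal interplanar spacing of a
#' [WoodModelParams-class].
#'
#' @param x object.
#' @return the extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("intensitySigma", function(x) standardGeneric("intensitySigma"))
#' @rdname accessors
#' @export
setGeneric("fittedParams", function(x) standardGeneric("fittedParams"))
#' @rdname accessors
#' @export
setGeneric("derivedStructure", function(x) standardGeneric("derivedStructure"))
#' @rdname accessors
#' @export
setGeneric("perTermProfiles", function(x) standardGeneric("perTermProfiles"))
#' @rdname accessors
#' @export
setGeneric("d100", function(x) standardGeneric("d100"))
#' @rdname accessors
#' @export
setGeneric("sldRho", function(x) standardGeneric("sldRho"))

#' @rdname accessors
#' @export
setMethod("qValues", "Profile1D", function(x) x@q)
#' @rdname accessors
#' @export
setMethod("intensity", "Profile1D", function(x) x@I)
#' @rdname accessors
#' @export
setMethod("intensitySigma", "Profile1D", function(x) x@sigma)
#' @rdname accessors
#' @export
setMethod("fittedParams", "FitResult", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("derivedStructure", "FitResult", function(x) x@derived)
#' @rdname accessors
#' @export
setMethod("perTermProfiles", "FitResult", function(x) x@perTerm)
#' @rdname accessors
#' @export
setMethod("d100", "WoodModelParams", function(x) sqrt(3) / 2 * x@aCC)
#' @rdname accessors
#' @export
setMethod("sldRho", "SLDValue", function(x) x@rho)

#' Number of points in a profile
#' @param x a [Profile1D-class].
#' @export
setMethod("length", "Profile1D", function(x) length(x@q))

#' Coerce a Profile1D to a data.frame
#'
#' @param x a [Profile1D-class].
#' @param ... unused.
#' @return data.frame with columns q, I, sigma.
#' @export
setMethod("as.data.frame", "Profile1D", function(x, ...) {
  data.frame(q = x@q, I = x@I, sigma = x@sigma)
})

#' Extract model parameters as a named numeric vector
#'
#' @param params a [WoodModelParams-class].
#' @return named numeric vector of the eleven model parameters.
#' @export
paramsToVector <- function(params) {
  stopifnot(is(params, "WoodModelParams"))
  c(A_mf = params@A_mf, R_mean = params@R_mean, R_sd = params@R_sd,
    aCC = params@aCC, g = params@g, N = params@N,
    A_b = params@A_b, sigma_b = params@sigma_b,
    B_pl = params@B_pl, alpha = params@alpha, C_bg = params@C_bg)
}

#' Build model parameters from a named vector
#'
#' Inverse of [paramsToVector()]; missing names take the constructor
#' defaults of [WoodModelParams()].
#'
#' @param v named numeric vector.
#' @return a [WoodModelParams-class].
#' @export
paramsFromVector <- function(v) {
  do.call(WoodModelParams, as.list(v))
}

setMethod("show", "Profile1D", function(object) {
  cat(sprintf("Profile1D: %d points, q in [%.4g, %.4g] 1/A (%s units)\n",
              length(object@q),
              if (length(object@q)) min(object@q) else NA,
              if (length(object@q)) max(object@q) else NA,
              if (object@absolute) "absolute" else "relative"))
  if (!is.null(object@meta$merged))
    cat("  merged from", object@meta$merged, "configurations\n")
})

setMethod("show", "Material", function(object) {
  f <- paste0(names(object@formula), object@formula, collapse = " ")
  cat(sprintf("Material '%s': %s, %.3f g/cm^3, %g exchangeable H\n",
              object@name, f, object@massDensity, object@nExchangeableH))
})

setMethod("show", "SLDValue", function(object) {
  cat(sprintf("SLD%s: %.4g 1/A^2 (%.3f x 1e-6 1/A^2)\n",
              if (is.na(object@material)) "" else paste0(" [", object@material, "]"),
              object@rho, object@rho * 1e6))
})

setMethod("show", "DetectorFrame", function(object) {
  g <- object@geometry
  cat(sprintf(
    "DetectorFrame: %d x %d pixels, lambda %.2f A, sdd %.3g m, %d masked\n",
    nrow(object@counts), ncol(object@counts), g@wavelength, g@sdd / 1000,
    sum(object@mask)))
})

setMethod("show", "WoodModelParams", function(object) {
  v <- paramsToVector(object)
  cat("WoodModelParams:\n")
  print(signif(v, 4))
  cat(sprintf("  d100 = %.2f A, bundle diameter = %.2f nm\n",
              d100(object), 2 * sqrt(2) / object@sigma_b / 10))
})

setMethod("show", "DerivedStructure", function(object) {
  cat(sprintf(paste0(
    "DerivedStructure: bundle diameter %.2f nm, ",
    "interfibrillar distance %.2f nm, packing peak %.4f 1/A\n"),
    object@bundleDiameter, object@interfibrillarDistance, object@peakQ))
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@convergence$status, ")\n", sep = "")
  cat(sprintf("  chi2/dof = %.3g, best start %d of %d\n",
              object@chi2Reduced, object@convergence$bestStart,
              length(object@convergence$objectives)))
  v <- paramsToVector(object@params)
  free <- names(object@stderr)
  for (nm in names(v)) {
    if (nm %in% free)
      cat(sprintf("  %-8s %.5g +/- %.2g\n", nm, v[[nm]], object@stderr[[nm]]))
    else
      cat(sprintf("  %-8s %.5g (frozen)\n", nm, v[[nm]]))
  }
  show(object@derived)
})

setMethod("show", "PolymerSolutionFit", function(object) {
  cat(sprintf(
    "PolymerSolutionFit (%s): Rg = %.2f +/- %.2f A (%.2f nm), I0 = %.4g, bg = %.4g, window [%.4g, %.4g] 1/A\n",
    object@method, object@Rg, object@RgStderr, object@Rg / 10, object@I0,
    object@background, object@fitWindow[1], object@fitWindow[2]))
})
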