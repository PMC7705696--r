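## Shape parameters sampled by Latin-hypercube multistart; the four
## amplitudes (A_mf, A_b, B_pl, C_bg) enter the model linearly and get their
## starting values from a non-negative linear least-squares solve instead.
.SHAPE_PARS <- c("R_mean", "R_sd", "aCC", "g", "sigma_b", "alpha", "N")
.AMP_PARS <- c("A_mf", "A_b", "B_pl", "C_bg")

# model intensity from a working parameter vector (named, full 11 params)
.modelFromVector <- function(q, v) {
  totalIntensity(q, paramsFromVector(v))
}

# design matrix of the four unit-amplitude terms for a linear amplitude solve
.termMatrix <- function(q, v) {
  p <- paramsFromVector(v)
  cbind(
    A_mf = if (p@R_mean > 0)
      sizeAveragedP(q, p@R_mean, p@R_sd) * paracrystalSF(q, p@aCC, p@g, p@N)
      else numeric(length(q)),
    A_b  = exp(-q^2 / (2 * p@sigma_b^2)),
    B_pl = q^(-p@alpha),
    C_bg = rep(1, length(q)))
}

# non-negative-clipped weighted linear LS for the amplitudes
.solveAmplitudes <- function(q, I, w, v, freeAmp) {
  X <- .termMatrix(q, v)[, freeAmp, drop = FALSE]
  sw <- sqrt(w)
  fixedPart <- .termMatrix(q, v)[, setdiff(.AMP_PARS, freeAmp),
                                 drop = FALSE]
  y <- I - if (ncol(fixedPart)) fixedPart %*% v[setdiff(.AMP_PARS, freeAmp)]
           else 0
  beta <- tryCatch(
    stats::lm.wfit(X, as.numeric(y), w)$coefficients,
    error = function(e) rep(0, length(freeAmp)))
  beta[!is.finite(beta) | beta < 0] <- 1e-12
  stats::setNames(as.numeric(beta), freeAmp)
}

#' Fit the three-term equatorial model to a scattering profile
#'
#' Weighted least-squares fit of [totalIntensity()] to a merged equatorial
#' profile, using Levenberg-Marquardt local optimisation
#' (\code{minpack.lm::nls.lm}) from \code{nStarts} Latin-hypercube starting
#' points for the nonlinear shape parameters; amplitude starting values are
#' obtained per start by a linear least-squares solve, and the first start
#' is data-informed (the microfibril spacing is read off the packing-peak
#' position when the fit window covers it). The best local optimum is
#' returned. Fits are deterministic given \code{config@seed}.
#'
#' The data are normalised internally by the maximum intensity in the fit
#' window, which makes the optimisation exactly scale-equivariant: rescaling
#' I and sigma by a constant rescales fitted amplitudes by the same constant
#' and leaves shape parameters untouched.
#'
#' Points with sigma = 0 (e.g. noise-free synthetic data) are assigned a
#' uniform 0.01 percent relative uncertainty so that weighting remains
#' defined.
#'
#' @param profile a [Profile1D-class] with at least 30 points inside the fit
#'   window.
#' @param config a [FitConfig-class].
#' @return a [FitResult-class]. Parameters that ended within 1e-6 (relative)
#'   of a finite bound are listed in \code{convergence$atBounds}.
#' @examples
#' \donttest{
#' truth <- WoodModelParams()
#' prof <- generateProfile(truth, noiseLevel = 0.02, seed = 7)
#' fit <- fitEquatorial(prof, FitConfig(nStarts = 4, seed = 1))
#' derivedStructure(fit)
#' }
#' @export
fitEquatorial <- function(profile, config = FitConfig()) {
  validObject(profile); validObject(config)
  inWin <- profile@q >= config@qRange[1] & profile@q <= config@qRange[2]
  q <- profile@q[inWin]; I <- profile@I[inWin]; sig <- profile@sigma[inWin]
  if (length(q) < 30L)
    stop("need >= 30 points in the fit window; have ", length(q))
  if (any(sig == 0))
    sig[sig == 0] <- 1e-4 * pmax(abs(I[sig == 0]), 1e-12 * max(abs(I)))

  ## exact scale equivariance: normalise by max I in window
  s <- max(abs(I))
  I <- I / s; sig <- sig / s

  frozen <- config@frozen
  defaults <- paramsToVector(WoodModelParams())
  freeShape <- setdiff(.SHAPE_PARS, names(frozen))
  freeAmp <- setdiff(.AMP_PARS, names(frozen))
  free <- c(freeShape, freeAmp)
  lower <- config@lower[free]; upper <- config@upper[free]

  baseVec <- defaults
  for (nm in names(frozen)) baseVec[nm] <- frozen[[nm]]
  # frozen amplitudes were given on the data scale
  for (nm in intersect(names(frozen), .AMP_PARS)) baseVec[nm] <- frozen[[nm]] / s

  useLog <- config@loss == "log"
  residFun <- function(par) {
    v <- baseVec
    v[free] <- par
    m <- .modelFromVector(q, v)
    if (useLog) {
      pos <- m > 0 & I > 0
      r <- numeric(length(q))
      r[pos] <- (log(I[pos]) - log(m[pos])) / (sig[pos] / abs(I[pos]))
      r[!pos] <- (I[!pos] - m[!pos]) / sig[!pos]
      r
    } else (I - m) / sig
  }

  ## Latin-hypercube starts for the shape parameters
  set.seed(as.integer(config@seed))
  nS <- as.integer(config@nStarts)
  loS <- lower[freeShape]; hiS <- upper[freeShape]
  hiS[!is.finite(hiS)] <- loS[!is.finite(hiS)] + 1
  U <- if (length(freeShape))
    lhs::randomLHS(nS, length(freeShape)) else matrix(0, nS, 0)
  starts <- lapply(seq_len(nS), function(i) {
    sv <- loS + U[i, ] * (hiS - loS)
    names(sv) <- freeShape
    v <- baseVec; v[freeShape] <- sv
    amp <- .solveAmplitudes(q, I, 1 / sig^2, v, freeAmp)
    amp <- pmin(pmax(amp, lower[freeAmp]),
                ifelse(is.finite(upper[freeAmp]), upper[freeAmp], Inf))
    c(sv, amp)[free]
  })
  ## replace the first start by a data-informed one: spacing read off the
  ## packing-peak position (standard practice), remaining shapes at
  ## mid-bounds; guards against the aCC/g smearing degeneracy
  pkWin <- q > 0.07 & q < 0.28
  if ("aCC" %in% freeShape && sum(pkWin) >= 5L) {
    qStar <- q[pkWin][which.max(I[pkWin])]
    sv <- (loS + hiS) / 2
    if ("sigma_b" %in% freeShape)
      sv[["sigma_b"]] <- sqrt(loS[["sigma_b"]] * hiS[["sigma_b"]])
    sv[["aCC"]] <- min(max(2 * pi / (sqrt(3) / 2 * qStar), loS[["aCC"]]),
                       hiS[["aCC"]])
    v <- baseVec; v[freeShape] <- sv
    amp <- .solveAmplitudes(q, I, 1 / sig^2, v, freeAmp)
    amp <- pmin(pmax(amp, lower[freeAmp]),
                ifelse(is.finite(upper[freeAmp]), upper[freeAmp], Inf))
    starts[[1L]] <- c(sv, amp)[free]
  }

  runs <- lapply(seq_len(nS), function(i) {
    tryCatch(
      minpack.lm::nls.lm(par = starts[[i]], lower = lower, upper = upper,
                         fn = residFun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) e)
  })
  okRun <- !vapply(runs, inherits, TRUE, what = "condition")
  if (!any(okRun)) {
    diag <- vapply(runs, function(r) conditionMessage(r), "")
    stop("all ", nS, " starts failed to converge:\n",
         paste(sprintf("  start %d: %s", seq_len(nS), diag), collapse = "\n"))
  }
  obj <- rep(Inf, nS)
  obj[okRun] <- vapply(runs[okRun], function(r) sum(r$fvec^2), 0)
  best <- which.min(obj)
  fit <- runs[[best]]

  par <- fit$par
  dof <- max(length(q) - length(par), 1L)
  chi2red <- sum(fit$fvec^2) / dof
  stderr <- rep(NA_real_, length(par)); names(stderr) <- names(par)
  covm <- tryCatch(chol2inv(chol(fit$hessian)), error = function(e) NULL)
  if (!is.null(covm)) stderr <- sqrt(pmax(diag(covm) * chi2red, 0))
  names(stderr) <- names(par)

  atB <- names(par)[
    (is.finite(lower) & abs(par - lower) <= 1e-6 * pmax(abs(lower), 1)) |
    (is.finite(upper) & abs(par - upper) <= 1e-6 * pmax(abs(upper), 1))]
  if (length(atB))
    warning("parameter(s) at bounds: ", paste(atB, collapse = ", "))

  ## back to data scale
  vFit <- baseVec; vFit[free] <- par
  for (nm in .AMP_PARS) vFit[nm] <- vFit[nm] * s
  stderr[intersect(names(stderr), .AMP_PARS)] <-
    stderr[intersect(names(stderr), .AMP_PARS)] * s
  params <- paramsFromVector(vFit)

  perTerm <- data.frame(
    q = q,
    microfibril = modelTerm(q, params, "microfibril"),
    bundle = modelTerm(q, params, "bundle"),
    powerlaw = modelTerm(q, params, "powerlaw"),
    background = modelTerm(q, params, "background"))
  perTerm$total <- perTerm$microfibril + perTerm$bundle + perTerm$powerlaw +
    perTerm$background

  res <- new("FitResult", params = params, stderr = stderr,
             chi2Reduced = chi2red, derived = deriveStructure(params),
             perTerm = perTerm,
             convergence = list(
               status = fit$message, nEval = fit$niter,
               bestStart = best, objectives = obj, atBounds = atB),
             data = Profile1D(q, I * s, sig * s, absolute = profile@absolute))

  hw <- params@sigma_b * sqrt(2 * log(2))
  pk <- res@derived@peakQ
  if (is.finite(pk) && hw > pk)
    warning("bundle Gaussian half-maximum q (", signif(hw, 3),
            ") exceeds the packing-peak position (", signif(pk, 3),
            "): bundle and microfibril terms overlap pathologically")
  res
}

#' Derive structural quantities from fitted model parameters
#'
#' bundle diameter from the Gaussian width via the cross-section Guinier law
#' ([bundleDiameterFromSigma()]), interfibrillar center-to-center distance
#' aCC converted to nm, and the packing-peak position from
#' [peakPosition()].
#'
#' @param params a [WoodModelParams-class].
#' @param convention Guinier convention, see [bundleDiameterFromSigma()].
#' @return a [DerivedStructure-class]. A warning (not an error) is issued if
#'   the bundle diameter does not exceed the interfibrillar distance, which
#'   is physically implausible for bundles of several microfibrils.
#' @examples
#' deriveStructure(WoodModelParams(aCC = 43, sigma_b = 0.0157))
#' @export
deriveStructure <- function(params, convention = "cross_section") {
  validObject(params)
  D <- bundleDiameterFromSigma(params@sigma_b, convention)
  aNm <- params@aCC / 10
  pk <- if (params@A_mf > 0)
    peakPosition(params)
  else suppressWarnings(peakPosition(params))
  if (D <= aNm)
    warning("bundle diameter (", signif(D, 3),
            " nm) <= interfibrillar distance (", signif(aNm, 3),
            " nm): physically implausible fit")
  new("DerivedStructure", bundleDiameter = D, interfibrillarDistance = aNm,
      peakQ = pk)
}

#' Decompose a profile into fitted model contributions
#'
#' Returns every model term evaluated on the data grid together with
#' "data minus the other terms" residual curves; \code{dataFromBundles} is
#' the experimental intensity minus the fitted microfibril, power-law and
#' background terms — the construction used to isolate the bundle
#' contribution in equatorial wood data.
#'
#' @param profile the fitted [Profile1D-class].
#' @param result the [FitResult-class] obtained on this profile.
#' @return data.frame with columns q, data, sigma, microfibril, bundle,
#'   powerlaw, background, total, dataFromBundles, residual.
#' @export
decomposeContributions <- function(profile, result) {
  stopifnot(is(profile, "Profile1D"), is(result, "FitResult"))
  q <- result@perTerm$q
  inWin <- profile@q >= min(q) - 1e-12 & profile@q <= max(q) + 1e-12
  if (sum(inWin) != length(q) ||
      max(abs(profile@q[inWin] - q)) > 1e-9 * max(q))
    stop("profile q grid does not match the grid the model was fitted on")
  pt <- result@perTerm
  data.frame(
    q = q, data = profile@I[inWin], sigma = profile@sigma[inWin],
    microfibril = pt$microfibril, bundle = pt$bundle,
    powerlaw = pt$powerlaw, background = pt$background, total = pt$total,
    dataFromBundles = profile@I[inWin] - pt$microfibril - pt$powerlaw -
      pt$background,
    residual = profile@I[inWin] - pt$total)
}

#' Residual-resampling bootstrap uncertainties for an equatorial fit
#'
#' Standardised residuals of the best fit are resampled with replacement,
#' scaled back by the per-point uncertainties and added to the fitted model
#' to form bootstrap replicates, each refitted (single start from the best
#' parameters). Percentile intervals are returned. Seeded and reproducible.
#'
#' @param profile a [Profile1D-class].
#' @param config a [FitConfig-class]; \code{config@seed} also seeds the
#'   resampling.
#' @param nBoot number of bootstrap replicates (>= 50).
#' @param level interval coverage level (default 0.95).
#' @return list with elements \code{intervals} (data.frame: parameter,
#'   lower, upper, estimate), \code{replicates} (matrix of refitted free
#'   parameters) and \code{fit} (the base [FitResult-class]).
#' @export
bootstrapUncertainty <- function(profile, config = FitConfig(),
                                 nBoot = 100L, level = 0.95) {
  if (nBoot < 50L) stop("nBoot must be >= 50")
  base <- suppressWarnings(fitEquatorial(profile, config))
  q <- base@data@q; sig <- base@data@sigma
  m <- base@perTerm$total
  resid <- (base@data@I - m) / ifelse(sig > 0, sig, 1)
  free <- names(base@stderr)
  cfg1 <- config
  cfg1@nStarts <- 1
  set.seed(as.integer(config@seed) + 104729L)
  reps <- matrix(NA_real_, nBoot, length(free),
                 dimnames = list(NULL, free))
  fails <- 0L
  for (b in seq_len(nBoot)) {
    Ib <- m + sample(resid, length(resid), replace = TRUE) *
      ifelse(sig > 0, sig, 1)
    pb <- Profile1D(q, Ib, sig)
    fb <- tryCatch(
      suppressWarnings(.refitFrom(pb, cfg1, paramsToVector(base@params))),
      error = function(e) NULL)
    if (is.null(fb)) fails <- fails + 1L
    else reps[b, ] <- paramsToVector(fb)[free]
  }
  if (fails / nBoot > 0.2)
    stop("bootstrap refit failure rate ", round(100 * fails / nBoot),
         "% exceeds 20% (", fails, "/", nBoot, " failed)")
  a <- (1 - level) / 2
  qs <- apply(reps, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
  list(intervals = data.frame(parameter = free, lower = qs[1, ],
                              upper = qs[2, ],
                              estimate = paramsToVector(base@params)[free],
                              row.names = NULL),
       replicates = reps, fit = base)
}

# single LM refit from a given full parameter vector (bootstrap helper)
.refitFrom <- function(profile, config, startVec) {
  inWin <- profile@q >= config@qRange[1] & profile@q <= config@qRange[2]
  q <- profile@q[inWin]; I <- profile@I[inWin]; sig <- profile@sigma[inWin]
  if (any(sig == 0))
    sig[sig == 0] <- 1e-4 * pmax(abs(I[sig == 0]), 1e-12 * max(abs(I)))
  s <- max(abs(I)); I <- I / s; sig <- sig / s
  frozen <- config@frozen
  free <- c(setdiff(.SHAPE_PARS, names(frozen)),
            setdiff(.AMP_PARS, names(frozen)))
  baseVec <- startVec
  for (nm in intersect(names(baseVec), .AMP_PARS)) baseVec[nm] <- baseVec[nm] / s
  residFun <- function(par) {
    v <- baseVec; v[free] <- par
    (I - .modelFromVector(q, v)) / sig
  }
  lower <- config@lower[free]; upper <- config@upper[free]
  start <- pmin(pmax(baseVec[free], lower),
                ifelse(is.finite(upper), upper, Inf))
  fit <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = residFun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-10, ptol = 1e-10))
  v <- baseVec; v[free] <- fit$par
  for (nm in .AMP_PARS) v[nm] <- v[nm] * s
  paramsFromVector(v)
}
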