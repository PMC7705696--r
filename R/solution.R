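#' Debye scattering function of a Gaussian polymer coil
#'
#' D(x) = 2 (e^{-x} + x - 1) / x^2 with x = q^2 Rg^2; D(0) = 1. The small-x
#' limit is evaluated by series to avoid cancellation.
#'
#' @param x q^2 Rg^2, >= 0 (vectorised).
#' @return Debye factor in (0, 1].
#' @examples
#' debyeFunction(1)  # 2/e ~ 0.73576
#' @export
debyeFunction <- function(x) {
  stopifnot(all(x >= 0))
  out <- numeric(length(x))
  small <- x < 1e-4
  xs <- x[small]
  out[small] <- 1 - xs / 3 + xs^2 / 12   # series
  xb <- x[!small]
  out[!small] <- 2 * (exp(-xb) + xb - 1) / xb^2
  out
}

# iterated flat-background estimate from the high-q tail (top fraction of q)
.tailBackground <- function(profile, tailFraction = 0.2) {
  n <- length(profile@q)
  tail <- profile@I[profile@q >= stats::quantile(profile@q, 1 - tailFraction)]
  if (length(tail) < 3L) return(0)
  mean(tail)
}

#' Guinier fit of an isotropic solution profile
#'
#' Weighted linear regression of ln(I - background) on q^2; Rg =
#' sqrt(-3 * slope). The flat background is first estimated from the high-q
#' tail. The Guinier validity condition q_max * Rg <= 1.3 is enforced by
#' iteratively shrinking the window from the high-q side and refitting; the
#' number of shrink iterations is recorded in the result's fit window
#' metadata (message).
#'
#' @param profile a [Profile1D-class] (isotropic solution scattering).
#' @param window initial q window, 1/A; default the full profile range.
#' @param background fixed flat background; if NULL (default), estimated
#'   from the top 20 percent of the q range and excluded from the fit window.
#' @return a [PolymerSolutionFit-class] with \code{method = "guinier"}.
#' @examples
#' q <- seq(0.01, 0.2, length.out = 60)
#' prof <- Profile1D(q, 100 * exp(-q^2 * 15^2 / 3), sigma = rep(0.5, 60))
#' fitGuinier(prof)
#' @export
fitGuinier <- function(profile, window = NULL, background = NULL) {
  validObject(profile)
  if (is.null(window)) window <- range(profile@q)
  fitBg <- is.null(background)
  if (fitBg) background <- .tailBackground(profile)
  tailSel <- profile@q >= stats::quantile(profile@q, 0.8)
  for (iter in 1:50) {
    sel <- profile@q >= window[1] & profile@q <= window[2]
    q <- profile@q[sel]; I <- profile@I[sel] - background
    sig <- profile@sigma[sel]
    pos <- I > 0
    if (sum(pos) < 8L)
      stop("window collapse: fewer than 8 positive points in [",
           signif(window[1], 3), ", ", signif(window[2], 3), "]")
    q <- q[pos]; I <- I[pos]; sig <- sig[pos]
    # var(ln I) = (sigma/I)^2; unweighted if sigma unavailable
    w <- if (all(sig > 0)) (I / sig)^2 else rep(1, length(I))
    fit <- stats::lm(log(I) ~ I(q^2), weights = w)
    slope <- stats::coef(fit)[[2]]
    seSlope <- summary(fit)$coefficients[2, 2]
    if (slope >= 0 || (is.finite(seSlope) && slope + 2 * seSlope >= 0))
      stop("no Guinier decay: regression slope of ln I vs q^2 is not ",
           "significantly negative")
    Rg <- sqrt(-3 * slope)
    I0 <- exp(stats::coef(fit)[[1]])
    if (max(q) * Rg > 1.3) {
      window[2] <- 1.3 / Rg   # shrink and refit
      next
    }
    if (fitBg) {
      # iterate the flat background: remove the extrapolated Guinier decay
      # from the high-q tail and re-estimate
      bgNew <- mean(profile@I[tailSel] -
                      I0 * exp(-profile@q[tailSel]^2 * Rg^2 / 3))
      if (abs(bgNew - background) > 1e-6 * max(abs(background), I0)) {
        background <- bgNew
        next
      }
    }
    return(new("PolymerSolutionFit", Rg = Rg,
               RgStderr = if (is.finite(seSlope))
                 3 * seSlope / (2 * Rg) else NA_real_,
               I0 = I0, background = background, method = "guinier",
               fitWindow = range(q)))
  }
  stop("window collapse: Guinier iteration did not converge in 50 rounds")
}

#' Debye (Gaussian-coil) fit of an isotropic solution profile
#'
#' Nonlinear weighted least-squares fit of
#' I(q) = I0 * D(q^2 Rg^2) + background, with D the Debye function of a
#' Gaussian chain. This is the default sizing model for flexible polymers
#' such as PEG: unlike the Guinier law it remains valid beyond q Rg ~ 1.3.
#'
#' @param profile a [Profile1D-class].
#' @param window q window, 1/A; default full range.
#' @param RgStart optional starting Rg (A); default from a Guinier pass, or
#'   1/q_mid if that fails.
#' @return a [PolymerSolutionFit-class] with \code{method = "debye"}.
#' @export
fitDebye <- function(profile, window = NULL, RgStart = NULL) {
  validObject(profile)
  if (is.null(window)) window <- range(profile@q)
  sel <- profile@q >= window[1] & profile@q <= window[2]
  q <- profile@q[sel]; I <- profile@I[sel]; sig <- profile@sigma[sel]
  if (length(q) < 8L) stop("need >= 8 points in the fit window")
  if (any(sig <= 0)) sig <- pmax(sig, 1e-4 * max(abs(I)))
  if (is.null(RgStart)) {
    RgStart <- tryCatch(fitGuinier(profile, window)@Rg,
                        error = function(e) 1 / stats::median(q))
  }
  bg0 <- .tailBackground(profile)
  start <- c(logRg = log(RgStart), I0 = max(I) - bg0, bg = bg0)
  fn <- function(p) {
    Rg <- exp(p[["logRg"]])
    (I - (p[["I0"]] * debyeFunction(q^2 * Rg^2) + p[["bg"]])) / sig
  }
  fit <- minpack.lm::nls.lm(par = start, fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  if (fit$info %in% c(0, 9) || !is.finite(sum(fit$fvec^2)))
    stop("Debye fit failed to converge: ", fit$message,
         " (info = ", fit$info, ")")
  Rg <- exp(fit$par[["logRg"]])
  se <- tryCatch({
    covm <- chol2inv(chol(fit$hessian))
    dof <- max(length(q) - 3L, 1L)
    sqrt(covm[1, 1] * sum(fit$fvec^2) / dof) * Rg   # delta method for exp
  }, error = function(e) NA_real_)
  new("PolymerSolutionFit", Rg = Rg, RgStderr = se,
      I0 = fit$par[["I0"]], background = fit$par[["bg"]],
      method = "debye", fitWindow = range(q))
}
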