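test_that("noise-free self-consistency: truth recovered with chi2 ~ 0", {
  truth <- softwoodTruth()
  prof <- generateProfile(truth, noiseLevel = 0, seed = 1)
  fit <- suppressWarnings(fitEquatorial(prof, FitConfig(nStarts = 6, seed = 4)))
  v <- paramsToVector(fit@params); tv <- paramsToVector(truth)
  for (nm in c("aCC", "sigma_b", "R_mean", "A_b", "B_pl"))
    expect_lt(abs(v[[nm]] - tv[[nm]]) / tv[[nm]], 0.01, label = nm)
  expect_lt(fit@chi2Reduced, 1e-3)
})

test_that("parameter recovery across the physical regime at default noise", {
  # truths spanning spacings 3.2-4.3 nm and diameters 8-18.5 nm
  cases <- expand.grid(aCC = c(32, 43), D = c(8, 18.5))
  errs <- apply(cases, 1, function(cs) {
    truth <- WoodModelParams(aCC = cs[["aCC"]],
                             sigma_b = 2 * sqrt(2) / (10 * cs[["D"]]))
    prof <- generateProfile(truth, noiseLevel = 0.02,
                            seed = 100 + cs[["aCC"]] + round(cs[["D"]]))
    fit <- suppressWarnings(fitEquatorial(prof, FitConfig(nStarts = 8, seed = 2)))
    c(aCC = abs(fit@params@aCC - cs[["aCC"]]) / cs[["aCC"]],
      D = abs(bundleDiameterFromSigma(fit@params@sigma_b) - cs[["D"]]) /
        cs[["D"]])
  })
  expect_lt(median(errs["aCC", ]), 0.02)
  expect_lt(median(errs["D", ]), 0.10)
})

test_that("a zero bundle amplitude is recovered as consistent with zero", {
  truth <- WoodModelParams(A_b = 0, A_mf = 0.012, B_pl = 1e-9, C_bg = 1e-3)
  prof <- generateProfile(truth, noiseLevel = 0.02, seed = 9)
  fit <- suppressWarnings(fitEquatorial(prof, FitConfig(nStarts = 8, seed = 3)))
  tol <- max(2 * fit@stderr[["A_b"]], 1e-3 * max(intensity(prof)))
  expect_lt(fit@params@A_b, tol)
})

test_that("fits are deterministic given the seed and exactly scale-equivariant", {
  truth <- softwoodTruth()
  prof <- generateProfile(truth, noiseLevel = 0.02, seed = 31)
  cfg <- FitConfig(nStarts = 6, seed = 17)
  f1 <- suppressWarnings(fitEquatorial(prof, cfg))
  f2 <- suppressWarnings(fitEquatorial(prof, cfg))
  expect_identical(paramsToVector(f1@params), paramsToVector(f2@params))
  expect_identical(f1@chi2Reduced, f2@chi2Reduced)
  # rescale I and sigma by c: amplitudes scale by c, shapes unchanged
  cc <- 137.5
  profC <- Profile1D(qValues(prof), cc * intensity(prof),
                     cc * intensitySigma(prof))
  f3 <- suppressWarnings(fitEquatorial(profC, cfg))
  v1 <- paramsToVector(f1@params); v3 <- paramsToVector(f3@params)
  amps <- c("A_mf", "A_b", "B_pl", "C_bg")
  shapes <- c("R_mean", "R_sd", "aCC", "g", "sigma_b")
  expect_equal(v3[amps], cc * v1[amps], tolerance = 1e-6)
  expect_equal(v3[shapes], v1[shapes], tolerance = 1e-6)
})

test_that("derived structure reproduces the closed forms and serialization round-trip", {
  p <- WoodModelParams(aCC = 43, sigma_b = 0.0157)
  d <- deriveStructure(p)
  expect_equal(d@bundleDiameter, 18.01, tolerance = 1e-3)
  expect_equal(d@interfibrillarDistance, 4.3, tolerance = 1e-12)
  p2 <- WoodModelParams(aCC = 32, sigma_b = 0.0157)
  expect_equal(deriveStructure(p2)@interfibrillarDistance, 3.2,
               tolerance = 1e-12)
  # identical after a vector round trip (determinism of derivation)
  pr <- paramsFromVector(paramsToVector(p))
  d2 <- deriveStructure(pr)
  expect_identical(d@bundleDiameter, d2@bundleDiameter)
  expect_identical(d@peakQ, d2@peakQ)
  # implausible fit (bundle smaller than spacing) warns, not errors
  expect_warning(deriveStructure(WoodModelParams(aCC = 43, sigma_b = 0.8,
                                                 A_mf = 0.01)),
                 "implausible")
})

test_that("decomposition terms sum to the model and isolate the bundle", {
  truth <- softwoodTruth()
  prof <- generateProfile(truth, noiseLevel = 0, seed = 1)
  fit <- suppressWarnings(fitEquatorial(prof, FitConfig(nStarts = 6, seed = 4)))
  expect_lt(fit@chi2Reduced, 1e-3)   # converged to the generating optimum
  dec <- decomposeContributions(prof, fit)
  expect_equal(dec$microfibril + dec$bundle + dec$powerlaw + dec$background,
               dec$total, tolerance = 1e-14)
  # on noise-free data, "data from bundles" equals the bundle term
  expect_equal(dec$dataFromBundles, dec$bundle, tolerance = 1e-3)
  # grid mismatch errors
  other <- generateProfile(truth, qGrid = defaultQGrid(0.003, 0.2),
                           noiseLevel = 0, seed = 1)
  expect_error(decomposeContributions(other, fit), "grid")
})

test_that("bundle residual of noisy data is centered on the bundle term", {
  truth <- softwoodTruth()
  prof <- generateProfile(truth, noiseLevel = 0.02, seed = 77)
  fit <- suppressWarnings(fitEquatorial(prof, FitConfig(nStarts = 8, seed = 6)))
  dec <- decomposeContributions(prof, fit)
  mid <- dec$q > 0.01 & dec$q < 0.05
  z <- (dec$dataFromBundles - dec$bundle)[mid] / dec$sigma[mid]
  expect_gt(t.test(z)$p.value, 0.01)
})

test_that("bootstrap intervals behave: near-zero width without noise, coverage with it", {
  truth <- WoodModelParams(A_mf = 0, A_b = 1, sigma_b = 0.0153,
                           B_pl = 1e-9, C_bg = 1e-3)
  qg <- defaultQGrid(0.002, 0.3, 20)
  frz <- list(alpha = 4, N = 4, A_mf = 0, R_mean = 12, R_sd = 2,
              aCC = 43, g = 0.2)
  cfg <- FitConfig(nStarts = 2, seed = 11, frozen = frz)
  # noise-free: interval widths ~ 0
  prof0 <- generateProfile(truth, qg, noiseLevel = 0, seed = 1)
  bs0 <- bootstrapUncertainty(prof0, cfg, nBoot = 50)
  w0 <- with(bs0$intervals, (upper - lower) / pmax(abs(estimate), 1e-12))
  expect_lt(max(w0), 1e-4)
  # noisy: ~95% of parameter intervals contain the truth over replicates
  tv <- paramsToVector(truth)
  hits <- 0L; total <- 0L
  widths1 <- widths2 <- numeric(0)
  for (r in 1:10) {
    prof <- generateProfile(truth, qg, noiseLevel = 0.02, seed = 300 + r)
    cfgr <- FitConfig(nStarts = 2, seed = 11 + r, frozen = frz)
    bs <- bootstrapUncertainty(prof, cfgr, nBoot = 60)
    inside <- with(bs$intervals, lower <= tv[parameter] &
                                 tv[parameter] <= upper)
    hits <- hits + sum(inside); total <- total + length(inside)
    widths1 <- c(widths1, with(bs$intervals, upper - lower))
    # doubled noise widens intervals
    profW <- generateProfile(truth, qg, noiseLevel = 0.04, seed = 300 + r)
    bsW <- bootstrapUncertainty(profW, cfgr, nBoot = 60)
    widths2 <- c(widths2, with(bsW$intervals, upper - lower))
  }
  expect_gte(hits / total, 0.80)   # binomial tolerance around 0.95
  expect_gt(median(widths2 / widths1), 1)
  expect_error(bootstrapUncertainty(prof0, cfg, nBoot = 10), ">= 50")
})
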