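test_that("cylinder cross-section amplitude matches its series and Bessel limits", {
  expect_identical(cylinderCSAmplitude(0), 1)
  expect_equal(cylinderCSAmplitude(1), 0.880101, tolerance = 1e-6)
  # continuity across the small-x switch
  expect_equal(cylinderCSAmplitude(1e-6 - 1e-12),
               cylinderCSAmplitude(1e-6 + 1e-12), tolerance = 1e-9)
  # first zero from an independent root-find on base besselJ
  z <- uniroot(function(x) besselJ(x, 1), c(3, 4.5), tol = 1e-10)$root
  expect_equal(z, 3.8317, tolerance = 1e-4)
  expect_lt(abs(cylinderCSAmplitude(z)), 1e-9)
})

test_that("size-averaged form factor matches degenerate and Monte-Carlo oracles", {
  q <- 10^seq(log10(0.002), log10(0.3), length.out = 50)
  # R_sd = 0 degenerates to the monodisperse form factor
  expect_equal(sizeAveragedP(q, 12, 0), cylinderCSAmplitude(q * 12)^2,
               tolerance = 1e-12)
  expect_equal(sizeAveragedP(0, 12, 2), 1, tolerance = 1e-12)
  # Monte-Carlo oracle at q = 0.2, R = 12 +/- 2 A (1e6 draws)
  set.seed(42)
  R <- rnorm(1.1e6, 12, 2); R <- R[R > 0][1:1e6]
  mc <- mean(cylinderCSAmplitude(0.2 * R)^2)
  expect_equal(sizeAveragedP(0.2, 12, 2), mc, tolerance = 1e-3)
})

test_that("paracrystal structure factor has its closed-form limits and matches the double-sum", {
  q <- 10^seq(log10(0.002), log10(0.3), length.out = 50)
  expect_equal(paracrystalSF(q, 43, 0.2, 1), rep(1, 50))
  expect_equal(paracrystalSF(1e-12, 43, 0.2, 4), 4, tolerance = 1e-6)
  # brute-force double sum over N sites, N <= 8
  bruteSF <- function(q, a, g, N) {
    d <- sqrt(3) / 2 * a; sig <- g * d
    S <- 0
    for (j in 1:N) for (k in 1:N)
      S <- S + exp(-q^2 * sig^2 * abs(j - k) / 2) * cos((j - k) * q * d)
    S / N
  }
  for (N in c(2, 4, 8))
    expect_equal(paracrystalSF(q, 43, 0.2, N), bruteSF(q, 43, 0.2, N),
                 tolerance = 1e-10)
  # principal maximum of the bare SF near 2 pi / d100
  qg <- seq(0.05, 0.3, length.out = 5000)
  pk <- qg[which.max(paracrystalSF(qg, 43, 0.2, 4))]
  expect_equal(pk, 2 * pi / (sqrt(3) / 2 * 43), tolerance = 0.05)
})

test_that("bundle Gaussian has its maximum at q = 0 and the defining width", {
  expect_equal(bundleTerm(0, 2.5, 0.01), 2.5)
  expect_equal(bundleTerm(0.01, 1, 0.01), exp(-0.5), tolerance = 1e-12)
  q <- seq(0.001, 0.3, length.out = 200)
  expect_true(all(diff(bundleTerm(q, 1, 0.0157)) < 0))
})

test_that("Gaussian width maps to bundle diameter via the cross-section Guinier law", {
  expect_equal(bundleDiameterFromSigma(0.0157), 18.01, tolerance = 1e-3)
  # D proportional to 1/sigma
  expect_equal(bundleDiameterFromSigma(0.0157 / 2),
               2 * bundleDiameterFromSigma(0.0157), tolerance = 1e-12)
  # spherical convention differs by sqrt(3)
  expect_equal(bundleDiameterFromSigma(0.0157, "spherical"),
               sqrt(3) * bundleDiameterFromSigma(0.0157), tolerance = 1e-12)
  expect_error(bundleDiameterFromSigma(0), "> 0")
})

test_that("Guinier round-trip on the exact oriented-disc intensity recovers the diameter", {
  # ln I of the disc form factor is linear in q^2 with slope -R_c^2/2
  for (D_nm in c(8, 13, 18.5)) {
    R <- D_nm * 10 / 2; Rc <- R / sqrt(2)
    q <- seq(1e-4, 1 / Rc, length.out = 200)
    I <- cylinderCSAmplitude(q * R)^2
    sl <- coef(lm(log(I) ~ I(q^2)))[[2]]
    expect_lt(sl, 0)
    Drec <- bundleDiameterFromSigma(1 / sqrt(-2 * sl))
    expect_lt(abs(Drec - D_nm) / D_nm, 0.03)
  }
})

test_that("total intensity is additive and linear in the amplitudes", {
  q <- 10^seq(log10(0.002), log10(0.3), length.out = 80)
  p <- WoodModelParams()
  tot <- totalIntensity(q, p)
  sumTerms <- modelTerm(q, p, "microfibril") + modelTerm(q, p, "bundle") +
    modelTerm(q, p, "powerlaw") + modelTerm(q, p, "background")
  expect_equal(tot, sumTerms, tolerance = 1e-14)
  expect_true(all(modelTerm(q, p, "microfibril") >= 0))
  # all amplitudes zero -> flat background
  p0 <- WoodModelParams(A_mf = 0, A_b = 0, B_pl = 0, C_bg = 0.7)
  expect_equal(totalIntensity(q, p0), rep(0.7, 80))
  # doubling one amplitude doubles that term only
  p2 <- WoodModelParams(A_b = 2 * p@A_b)
  expect_equal(totalIntensity(q, p2) - tot, modelTerm(q, p, "bundle"),
               tolerance = 1e-12)
})

test_that("pure power law has exact log-log slope", {
  q <- 10^seq(log10(0.005), log10(0.2), length.out = 60)
  p <- WoodModelParams(A_mf = 0, A_b = 0, B_pl = 1e-9, alpha = 4, C_bg = 0)
  sl <- coef(lm(log(totalIntensity(q, p)) ~ log(q)))[[2]]
  expect_equal(sl, -4, tolerance = 1e-3)
})

test_that("bundle term dominates the intensity over q = 0.01-0.05 1/A at softwood defaults", {
  p <- softwoodTruth()
  q <- 10^seq(log10(0.01), log10(0.05), length.out = 40)
  bundle <- modelTerm(q, p, "bundle")
  rest <- totalIntensity(q, p) - modelTerm(q, p, "background") -
    modelTerm(q, p, "powerlaw")
  expect_true(all(bundle / rest > 0.5))
  # and the implied diameter sits in the native-wood window
  D <- bundleDiameterFromSigma(p@sigma_b)
  expect_gt(D, 12); expect_lt(D, 19.01)
})

test_that("packing-peak position tracks 2 pi / d100", {
  # Bragg limit: g -> 0, N large
  for (a in c(32, 43)) {
    p <- WoodModelParams(aCC = a, g = 0.01, N = 8)
    expect_equal(peakPosition(p), 2 * pi / d100(p), tolerance = 0.011)
  }
  # grid-search oracle at a = 32, default disorder: form-factor modulated
  p32 <- WoodModelParams(aCC = 32)
  qg <- seq(0.05, 0.3, length.out = 4001)
  f <- sizeAveragedP(qg, p32@R_mean, p32@R_sd) *
    paracrystalSF(qg, p32@aCC, p32@g, p32@N)
  expect_equal(peakPosition(p32), qg[which.max(f)], tolerance = 1e-3)
  expect_equal(peakPosition(p32), 0.2040, tolerance = 5e-3)
  # monotone: larger spacing, smaller peak q
  pks <- vapply(c(32, 38, 43), function(a)
    peakPosition(WoodModelParams(aCC = a)), 0)
  expect_true(all(diff(pks) < 0))
  # no interior maximum -> boundary with warning
  expect_warning(peakPosition(WoodModelParams(aCC = 43), window = c(0.2, 0.3)),
                 "boundary")
})

test_that("parameter invariants are enforced", {
  expect_error(WoodModelParams(g = 0.6), "g must")
  expect_error(WoodModelParams(sigma_b = 0), "sigma_b")
  expect_error(WoodModelParams(alpha = 2.5), "alpha")
  expect_error(totalIntensity(c(-0.1, 0.1), WoodModelParams()))
  # round trip through the vector representation
  p <- WoodModelParams(aCC = 39.5, g = 0.17)
  expect_equal(paramsToVector(paramsFromVector(paramsToVector(p))),
               paramsToVector(p))
})
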