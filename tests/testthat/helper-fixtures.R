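# shared fixtures built in code

# hand-computed SLD oracle: sum of tabulated bound coherent scattering
# lengths (fm) over the molecular volume M / (rho N_A) in A^3
oracleSLD <- function(counts, bcoh, masses, density) {
  M <- sum(counts * masses)
  V <- M / (density * 6.02214076e23) * 1e24
  sum(counts * bcoh) * 1e-5 / V
}

# Sears values used by the oracle (independent of the package table's layout)
B <- c(H = -3.7390, D = 6.671, C = 6.6460, O = 5.803)
AM <- c(H = 1.008, D = 2.014, C = 12.011, O = 15.999)

# frozen oracle values (computed once from oracleSLD):
#   D2O  (D2, O1; 1.105):  6.361399e-06
#   H2O  (H2, O1; 0.997): -5.582473e-07
#   cellulose (C6 H10 O5; 1.60): 1.871985e-06
ORACLE_SLD <- list(
  d2o = 6.361399e-06, h2o = -5.582473e-07, cellulose = 1.871985e-06)

softwoodTruth <- function(...) WoodModelParams(aCC = 43,
                                               sigma_b = 2 * sqrt(2) / 185,
                                               ...)

# small, fast synthetic spec for reduction tests (single mid-length camera)
smallSpec <- function(seed = 1, countsScale = 2000, spread = 10, ...) {
  SyntheticSpec(truth = softwoodTruth(),
                geometries = defaultGeometries(sdd = 8000),
                orientationSpread = spread,
                countsScale = countsScale, seed = seed, ...)
}
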