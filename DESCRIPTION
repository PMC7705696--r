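Package: fibrilSANS
Title: Small-Angle Neutron Scattering Analysis of Cellulose Microfibril
    Bundles in Wood
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reduction and model-based analysis of anisotropic small-angle
    neutron scattering (SANS) from oriented plant cell walls. Two-dimensional
    detector frames are reduced to equatorial one-dimensional profiles by
    azimuthal sectoring and subtraction of the isotropic component, merged
    across detector distances and rebinned. The equatorial intensity is fitted
    with a three-term model: a paracrystalline stack of polydisperse cylindrical
    cellulose microfibrils, a Gaussian term interpreted through the
    cross-section Guinier law as scattering from microfibril bundles, and a
    power law from large pores and cell lumina. Derived quantities are the
    microfibril bundle diameter and the interfibrillar center-to-center
    spacing. Additional tools compute neutron scattering-length densities for
    contrast-variation planning, size flexible polymers (e.g. PEG) in solution
    via Guinier and Debye fits, and generate seeded synthetic frames and
    profiles with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    minpack.lm,
    lhs,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
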