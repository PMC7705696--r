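---
title: "Equatorial SANS analysis of microfibril bundles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equatorial SANS analysis of microfibril bundles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilSANS)
```

# The measurement and the model

A wood section mounted with its cell axis vertical is a fiber sample: the
lateral organisation of the cellulose microfibrils scatters into a
horizontal (equatorial) streak on the 2D detector, superimposed on an
isotropic background from incoherent scattering and unoriented structures.
The analysis chain is: map every pixel to (q, azimuth), subtract the
isotropic component at each q, merge the camera lengths, and fit the
resulting 1D equatorial profile with a three-term model

$$I(q) = A_{mf}\,\langle\Phi^2(qR)\rangle\,S_N(q)
       + A_b\,e^{-q^2/2\sigma_b^2} + B\,q^{-\alpha} + C.$$

**Microfibril term.** Microfibrils are modelled as long cylinders seen
perpendicular to their axis, with cross-section amplitude
$\Phi(x) = 2J_1(x)/x$ and a truncated-normal radius distribution
(default $R = 12 \pm 2$ Å, i.e. 2–3 nm thick fibrils). We use the local
monodisperse approximation $\langle\Phi^2\rangle S$ rather than
$\langle\Phi\rangle^2 S + (\langle\Phi^2\rangle - \langle\Phi\rangle^2)$:
simpler, and adequate at this modest polydispersity. The radius average
uses fixed-grid trapezoid quadrature over ±4 sd with 129 nodes, verified
against a $10^6$-draw Monte-Carlo average to 0.1%.

Packing is described by a finite one-dimensional paracrystal along the
hexagonal $\{100\}$ direction: spacing $d_{100} = (\sqrt3/2)\,a_{cc}$,
cumulative Gaussian displacement disorder of sd $g\,d_{100}$, and $N$
coherent planes,

$$S_N(q) = 1 + \frac2N \sum_{k=1}^{N-1} (N-k)\,F(q)^k \cos(kqd),
\qquad F(q) = e^{-q^2(gd)^2/2}.$$

$S_N(0) = N$ is finite, and the principal maximum sits at
$q^\ast \approx 2\pi/d_{100}$ — the 0.1–0.2 Å⁻¹ packing peak from which
the center-to-center spacing is read. A 1D stack is used instead of a
full 2D hexagonal paracrystal because only the peak position and breadth
are constrained by equatorial data of this kind; the form is isolated
behind `paracrystalSF()` so a 2D variant could be swapped in. The closed
form equals a brute-force double sum over sites to $10^{-10}$ relative
for $N \le 8$ (tested).

**Bundle term.** Lateral aggregates of microfibrils produce excess
low-q scattering without a clear correlation peak; it is modelled as a
Gaussian with its maximum at $q = 0$. Equating
$e^{-q^2/2\sigma_b^2}$ with the *cross-section* Guinier law
$e^{-q^2 R_c^2/2}$ — the appropriate form for the equatorial slice of
long oriented particles — gives $R_c = 1/\sigma_b$, and for a homogeneous
circular cross-section $R = \sqrt2 R_c$, hence
$D = 2\sqrt2/\sigma_b$. A `convention = "spherical"` switch exposes the
3D alternative $R_g = \sqrt3/\sigma_b$ (a constant factor $\sqrt3$
larger); the cross-section form is the default because the bundles are
long and oriented. With the default, the $\sigma_b$ window where the
bundle term dominates (0.01–0.05 Å⁻¹) maps to diameters covering the
8–19 nm regime of interest. Fitting the Gaussian to the exact oriented
disc intensity $\Phi^2(qR)$ over $qR_c < 1$ recovers the true diameter
to within 2% (the quartic term of $\ln\Phi^2$ biases the width by
$\sim$1%; tested at 8, 13 and 18.5 nm).

**Power law and background.** Sharp interfaces of large pores and cell
lumina give $I \propto q^{-4}$ (Porod); $\alpha$ is frozen at 4 by
default and can be freed in [3, 4]. A flat constant absorbs residual
incoherent background.

# Reduction choices

* **q map**: $q = 4\pi\sin\theta/\lambda$ with $2\theta = \arctan(r/SDD)$;
  azimuth is folded into the angular distance from the equator
  ([0°, 90°]) using the 180° periodicity of fiber patterns.
* **Isotropic estimator**: the mean over a reference band 60–90° from the
  equator (a 60°-wide band centered on the meridian), subtracted from the
  mean over the ±15° equator band, per q bin. A mean (not a minimum or
  median) is unbiased under Poisson noise. Negative differences are
  retained — clipping would bias the profile toward positive values.
* **Solid angle**: a $\cos^3 2\theta$ flat-detector weight; full
  instrument calibration (efficiency maps, transmission, absolute units)
  is out of scope, so profiles are analysed in relative units and the
  model amplitudes are relative too.
* **Bin q assignment**: each q bin reports the mean pixel q of its
  equator band rather than the bin center; on steep $q^{-4}$ segments the
  center would be biased by several percent.
* **Merging**: configurations are rescaled onto the longest-camera
  reference by least squares in the q overlap, processed outward in
  median-q order, then log-rebinned (default 40 bins per decade over
  0.002–0.3 Å⁻¹). Free per-configuration scale factors absorb the
  azimuthal-pixelation differences between cameras (coarse azimuth
  sampling near the beam center on short cameras).

# Fitting

Weighted least squares on linear intensity with $1/\sigma^2$ weights
(a log-intensity option exists for data spanning many decades), via
Levenberg–Marquardt with box bounds. Default bounds express the physical
regime: $R \in [8, 20]$ Å, $a_{cc} \in [25, 60]$ Å,
$\sigma_b \in [0.005, 0.05]$ Å⁻¹, $g \in [0.01, 0.45]$; $\alpha = 4$ and
$N = 4$ frozen unless freed.

The objective has a known near-degeneracy: a too-small $a_{cc}$ with
large $g$ (smeared peak) can come within ~2% of the true optimum.
Multistart (default 16) handles this: starts are Latin-hypercube samples
of the shape parameters, except the first, which is data-informed — the
spacing is initialised from the packing-peak argmax in the data
(standard practice when reading fiber diffraction patterns) — and all
amplitude starting values come from a non-negative linear least-squares
solve, since the amplitudes enter the model linearly. Points with
$\sigma = 0$ (noise-free synthetic data) receive a uniform 0.01%
relative uncertainty so weights stay defined.

Two properties are guaranteed by construction and tested:

* **Seeded determinism** — identical data and seed give bit-identical
  results.
* **Exact scale equivariance** — data are normalised internally by the
  maximum intensity in the fit window; rescaling $I, \sigma$ by $c$
  rescales the four amplitudes by $c$ and leaves shape parameters
  untouched.

Standard errors come from the LM covariance scaled by
$\chi^2_\nu$; `bootstrapUncertainty()` provides residual-resampling
percentile intervals (seeded, single-start refits from the best fit)
whose ~95% coverage is verified in a seeded replicate study. An
identifiability guard warns when the fitted Gaussian's half-maximum q
exceeds the packing-peak position.

# Solution sizing

For PEG in solution the default model is the Debye Gaussian-coil
function $I(q) = I_0\,\frac{2}{x^2}(e^{-x}+x-1) + b$, $x = q^2R_g^2$,
evaluated by series below $x = 10^{-4}$ to avoid cancellation. A Guinier
fit (weighted regression of $\ln(I-b)$ on $q^2$, $R_g = \sqrt{-3\,
\mathrm{slope}}$) is also provided because it is the classical low-q
analysis; it enforces $q_{max}R_g \le 1.3$ by shrinking the window and
iterates a flat-background estimate from the high-q tail. A fit is
rejected ("no Guinier decay") when the slope is not significantly
negative. The two estimators agree within 10% on Debye-generated data
restricted to $qR_g < 1$ (tested); outputs are labelled by method since
they estimate different functionals on real, non-ideal data.

# The synthetic-data generator

The generator emulates a three-configuration pinhole SANS measurement of
a fiber sample: λ = 6.0 Å; sample–detector distances 1.5, 8 and 39 m;
128 × 128 pixels of 7.5 mm, beam center in the frame center, a 3-pixel
beam-stop mask; together covering q ≈ 0.002–0.3 Å⁻¹. Anisotropic terms
(microfibril, bundle, *and* power law — in wood, oriented lumina and
pores also streak equatorially) are multiplied by a wrapped-Gaussian
azimuth weight centered on the equator (default spread 10°, normalised
to unit mean over the circle), an isotropic flat term is added, the
whole is scaled by the solid-angle weight and a counts scale, and counts
are drawn Poisson. The default counts scale (2000 expected counts per
unit model intensity) yields per-configuration totals of roughly
$10^5$–$10^8$ counts and per-bin relative errors of 0.5–3%, typical of a
well-exposed measurement. Per-frame child seeds derive from the master
seed by a fixed counter scheme (seed + 7919·i); there is no hidden
global RNG state.

Default truth values place the simulation in the native-softwood regime:
$a_{cc} = 43$ Å (4.3 nm spacing), $\sigma_b = 2\sqrt2/185$ Å⁻¹
(18.5 nm bundles), amplitude ratios chosen so the bundle term dominates
the background-subtracted intensity over 0.01–0.05 Å⁻¹ and the intensity
spans ~4.5 decades, as in measured equatorial wood profiles.

What the generator does **not** emulate: instrument resolution smearing
(wavelength spread, collimation), detector efficiency variations,
multiple scattering, sample absorption, and inter-sample structural
heterogeneity. Passing recovery tests therefore demonstrates the
correctness and statistical calibration of the reduction and fitting
chain — not that real wood data are free of those systematics.

# Numerical and design notes

* $\Phi(x)$ switches to its series $1 - x^2/8$ below $x = 10^{-6}$;
  the Debye function to $1 - x/3 + x^2/12$ below $10^{-4}$.
* `peakPosition()` locates the microfibril-term maximum on a 2001-point
  grid over (0.05, 0.3) Å⁻¹ refined by golden-section search; if the
  maximum lies on the window boundary it returns the boundary with a
  warning rather than failing. Note that the cylinder form factor pulls
  the argmax a little below $2\pi/d_{100}$: about 0.5% at
  $a_{cc} = 43$ Å and 1% at 32 Å with $R = 12 \pm 2$ Å, shrinking with
  thinner fibrils or larger N.
* Deuterium exchange is mean-field fractional stoichiometry (SLD is
  linear in the scattering lengths, so this is exact for the mean), with
  the molecular volume of the protonated structure.
* Material presets (crystalline cellulose C₆H₁₀O₅ at 1.60 g/cm³,
  lignin approximated as C₉H₁₀O₃ at 1.40, PEG repeat C₂H₄O at 1.125,
  D₂O, H₂O) ship as YAML with documented approximate densities; they are
  reasonable literature values, not claimed reproductions of any
  specific study's inputs.
* Problem sizes used in the shipped tests (three 128² frames, 40 bins
  per decade, 16 multistarts, 50–60 bootstrap replicates, 6–10 seeded
  replicates per statistical property) were chosen to make every
  statistical assertion stable at desk scale; all are parameters a user
  can raise.

# Known limitations

* Relative units only; absolute-intensity calibration is out of scope.
* The Gaussian-plus-Guinier reading of the bundle term assumes dilute,
  spatially separated bundles; if bundles are densely correlated the
  diameter is an effective, not literal, size.
* The 1D paracrystal is a deliberate simplification of 2D hexagonal
  packing; peak *position* (hence $a_{cc}$) is robust to this choice,
  absolute peak intensity is not.
* Guinier/Debye solution sizes are apparent sizes at finite
  concentration; no structure-factor correction is applied.

```{r session}
sessionInfo()
```
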