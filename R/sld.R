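## Bound coherent neutron scattering lengths (Sears compilation), fm,
## and standard atomic masses, g/mol. Static table: no network lookups.
.NEUTRON_TABLE <- data.frame(
  symbol = c("H", "D", "C", "N", "O", "S", "P", "Na", "Cl", "K",
             "Ca", "Si", "Mg", "Al", "Fe"),
  bCoh   = c(-3.7390, 6.671, 6.6460, 9.36, 5.803, 2.847, 5.13, 3.63,
             9.577, 3.67, 4.70, 4.1491, 5.375, 3.449, 9.45),
  mass   = c(1.008, 2.014, 12.011, 14.007, 15.999, 32.06, 30.974,
             22.990, 35.45, 39.098, 40.078, 28.085, 24.305, 26.982,
             55.845),
  stringsAsFactors = FALSE
)

.AVOGADRO <- 6.02214076e23

.lookupNeutron <- function(symbols) {
  i <- match(symbols, .NEUTRON_TABLE$symbol)
  if (anyNA(i)) {
    bad <- symbols[is.na(i)]
    stop("unknown element/isotope symbol(s): ", paste(bad, collapse = ", "),
         ". Known: ", paste(.NEUTRON_TABLE$symbol, collapse = ", "))
  }
  .NEUTRON_TABLE[i, , drop = FALSE]
}

#' Molecular volume of a material
#'
#' V = M / (density * N_A), expressed in Angstrom^3 per formula unit.
#'
#' @param material a [Material-class].
#' @return volume in A^3.
#' @export
molecularVolume <- function(material) {
  validObject(material)
  tab <- .lookupNeutron(names(material@formula))
  M <- sum(material@formula * tab$mass)           # g/mol
  M / (material@massDensity * .AVOGADRO) * 1e24   # cm^3 -> A^3
}

#' Compute the coherent neutron scattering-length density
#'
#' rho = sum_i count_i * b_coh,i / V, where V is the molecular volume
#' implied by the formula mass and the mass density. Scattering lengths are
#' taken from a bundled static table of bound coherent values (fm).
#'
#' @param material a [Material-class].
#' @return an [SLDValue-class] with rho in 1/A^2 and a per-element breakdown
#'   of the summed scattering length (fm).
#' @examples
#' computeSLD(Material("D2O", c(D = 2, O = 1), 1.105))  # ~6.36e-6 1/A^2
#' @export
computeSLD <- function(material) {
  validObject(material)
  tab <- .lookupNeutron(names(material@formula))
  bPer <- material@formula * tab$bCoh             # fm per element
  V <- molecularVolume(material)                  # A^3
  rho <- sum(bPer) * 1e-5 / V                     # fm = 1e-5 A
  comps <- tapply(bPer, names(material@formula), sum)
  new("SLDValue", rho = rho, components = as.numeric(comps) |>
        stats::setNames(names(comps)), material = material@name)
}

#' Scattering-length density after solvent H/D exchange
#'
#' Labile hydrogens exchange with the solvent: a fraction
#' \code{solventDFraction} of the \code{nExchangeableH} hydrogens per formula
#' unit is replaced by deuterium, treated mean-field as fractional
#' stoichiometry (SLD is linear in the scattering lengths, so the mean-field
#' composition gives the exact mean SLD). The molecular volume is that of the
#' protonated material: H/D substitution changes the mass but not the
#' structure.
#'
#' @param material a [Material-class] with \code{nExchangeableH} set.
#' @param solventDFraction deuterium fraction of the solvent, in [0, 1].
#' @return an [SLDValue-class].
#' @examples
#' cel <- Material("cellulose", c(C = 6, H = 10, O = 5), 1.60,
#'                 nExchangeableH = 3)
#' computeSLD(cel)
#' exchangeAdjustedSLD(cel, 1)   # all 3 OH hydrogens deuterated
#' @export
exchangeAdjustedSLD <- function(material, solventDFraction) {
  validObject(material)
  if (length(solventDFraction) != 1L || !is.finite(solventDFraction) ||
      solventDFraction < 0 || solventDFraction > 1)
    stop("solventDFraction must be a single number in [0, 1]")
  V <- molecularVolume(material)    # volume of the protonated structure
  f <- material@formula
  nEx <- material@nExchangeableH * solventDFraction
  if (nEx > 0) {
    f["H"] <- f[["H"]] - nEx
    f["D"] <- (if ("D" %in% names(f)) f[["D"]] else 0) + nEx
  }
  tab <- .lookupNeutron(names(f))
  bPer <- f * tab$bCoh
  rho <- sum(bPer) * 1e-5 / V
  comps <- tapply(bPer, names(f), sum)
  new("SLDValue", rho = rho,
      components = as.numeric(comps) |> stats::setNames(names(comps)),
      material = material@name)
}

#' Neutron contrast between two phases
#'
#' Small-angle scattering is sensitive only to scattering-length-density
#' differences between phases; the scattered intensity scales with the
#' squared difference.
#'
#' @param a,b [SLDValue-class] objects (or bare numerics in 1/A^2).
#' @return (rho_a - rho_b)^2, in 1/A^4. Symmetric; zero iff equal.
#' @examples
#' d2o <- computeSLD(Material("D2O", c(D = 2, O = 1), 1.105))
#' h2o <- computeSLD(Material("H2O", c(H = 2, O = 1), 0.997))
#' contrast(d2o, h2o)
#' @export
contrast <- function(a, b) {
  ra <- if (is(a, "SLDValue")) a@rho else as.numeric(a)
  rb <- if (is(b, "SLDValue")) b@rho else as.numeric(b)
  if (!is.finite(ra) || !is.finite(rb)) stop("SLDs must be finite")
  (ra - rb)^2
}

#' Bundled material presets
#'
#' Presets ship in a YAML file under \code{inst/extdata/materials.yaml} and
#' cover the phases relevant to contrast matching in PEG-impregnated wood:
#' crystalline cellulose, a lignin monomer approximation, the PEG repeat
#' unit, D2O and H2O. Densities are documented literature approximations.
#' A user file with the same layout can be supplied to override the bundle.
#'
#' @param name preset name; see [materialPresets()].
#' @param file optional path to a YAML preset file overriding the bundled one.
#' @return a [Material-class].
#' @examples
#' materialPreset("d2o")
#' sapply(materialPresets(), function(m) computeSLD(materialPreset(m))@rho)
#' @export
materialPreset <- function(name, file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "materials.yaml", package = "fibrilSANS",
                        mustWork = TRUE)
  defs <- yaml::read_yaml(file)
  if (!name %in% names(defs))
    stop("unknown preset '", name, "'. Available: ",
         paste(names(defs), collapse = ", "))
  d <- defs[[name]]
  Material(name = name, formula = unlist(d$formula),
           massDensity = d$density, nExchangeableH = d$n_exchangeable_H)
}

#' @rdname materialPreset
#' @export
materialPresets <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "materials.yaml", package = "fibrilSANS",
                        mustWork = TRUE)
  names(yaml::read_yaml(file))
}
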