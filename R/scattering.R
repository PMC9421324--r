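#' Coherent neutron scattering lengths
#'
#' Bound coherent scattering lengths for the elements (and deuterium) that
#' occur in skin-lipid model membranes, in femtometres. Values are the
#' standard tabulated neutron data (Sears compilation, as distributed with the
#' NIST activation/scattering-length resources).
#'
#' @return Named numeric vector of coherent scattering lengths (fm).
#' @export
#' @examples
#' neutron_scattering_lengths()[c("H", "D", "C")]
neutron_scattering_lengths <- function() {
  c(
    H  = -3.7390,
    D  =  6.6710,
    C  =  6.6460,
    N  =  9.3600,
    O  =  5.8030,
    S  =  2.8470,
    P  =  5.1300,
    Si =  4.1491
  )
}

#' Parse a chemical formula into element counts
#'
#' Accepts formulas such as `"C24H48O2"` or `"C24H2D47NO3"`. Deuterium is the
#' symbol `D`. Only element symbols with tabulated scattering lengths are
#' accepted.
#'
#' @param formula Character scalar, e.g. `"C24H48O2"`.
#' @return Named numeric vector of element counts.
#' @export
parse_chemical_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse chemical formula: ", formula)
  }
  known <- names(neutron_scattering_lengths())
  counts <- numeric(0)
  for (tok in tokens) {
    sym <- gsub("[0-9]", "", tok)
    n <- gsub("[^0-9]", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    if (!sym %in% known) {
      stop("unknown element or isotope symbol '", sym, "' in formula ", formula)
    }
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0) + n
  }
  counts
}

# atomic masses (g/mol) for molecular-volume computation
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, P = 30.974, Si = 28.085
)

#' Molecular scattering length and volume from a formula
#'
#' @param formula Chemical formula string (see [parse_chemical_formula()]).
#' @param density Mass density in g/cm^3.
#' @return List with `b_fm` (summed coherent scattering length, fm),
#'   `mw` (g/mol) and `volume_A3` (molecular volume, cubic Angstrom).
#' @export
molecular_scattering <- function(formula, density) {
  stopifnot(is.numeric(density), density > 0)
  counts <- parse_chemical_formula(formula)
  b <- neutron_scattering_lengths()
  mw <- sum(counts * .atomic_masses[names(counts)])
  # V [A^3] = MW / (rho * N_A) with N_A = 0.60221 molecules * A^-3 * cm^3/mol
  list(
    b_fm = sum(counts * b[names(counts)]),
    mw = mw,
    volume_A3 = mw / (density * 0.60221)
  )
}

#' Scattering length density of a pure compound
#'
#' @inheritParams molecular_scattering
#' @return SLD in units of 1e-6 / Angstrom^2.
#' @export
#' @examples
#' sld_from_formula("H2O", 0.997)   # about -0.56
#' sld_from_formula("D2O", 1.107)   # about  6.37
sld_from_formula <- function(formula, density) {
  ms <- molecular_scattering(formula, density)
  # b in fm = 1e-5 A; SLD = sum(b)/V -> 1e-5/A^2; report in 1e-6/A^2
  ms$b_fm * 1e-5 / ms$volume_A3 * 1e6
}

#' Scattering length density of a D2O/H2O mixture
#'
#' Linear volume-fraction mixing of the pure-water SLDs.
#'
#' @param frac_d2o D2O volume percentage in \[0, 100\].
#' @return SLD in 1e-6 / Angstrom^2.
#' @export
water_mix_sld <- function(frac_d2o) {
  stopifnot(all(frac_d2o >= 0 & frac_d2o <= 100))
  f <- frac_d2o / 100
  f * sld_from_formula("D2O", 1.107) + (1 - f) * sld_from_formula("H2O", 0.997)
}

#' Water contrast weight relative to the 8% null point
#'
#' The 8% D2O mixture is treated as exactly zero contrast (the null-contrast
#' assumption of the contrast-variation protocol): the mixture SLD is offset
#' so the weight is 0 at 8% and 1 at 100% D2O. Water-associated Fourier
#' components of the unit cell scale linearly with this weight.
#'
#' @inheritParams water_mix_sld
#' @return Dimensionless weight, 0 at 8% and 1 at 100% D2O.
#' @export
water_contrast_weight <- function(frac_d2o) {
  s8 <- water_mix_sld(8)
  (water_mix_sld(frac_d2o) - s8) / (water_mix_sld(100) - s8)
}
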