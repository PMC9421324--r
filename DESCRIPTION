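Package: lamellar
Title: Neutron Diffraction and FTIR Analysis of Skin Lipid Lamellar Phases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for lamellar neutron diffraction and Fourier
    transform infrared (FTIR) spectroscopy of stratum corneum lipid model
    membranes forming the ~12.6 nm long periodicity phase (LPP). Reduces 1D
    diffraction patterns to order-indexed structure-factor amplitudes
    (Pearson VII peak fitting, Lorentz and absorption corrections), determines
    phase signs by D2O/H2O contrast variation, reconstructs centrosymmetric
    scattering-length-density profiles by Fourier synthesis, localizes
    deuterated lipid chains through difference profiles with relative-absolute
    scaling, and analyses FTIR thermotropic traces and methylene scissoring
    bands (transition midpoints, Lorentzian triplet fits, orthorhombic/middle
    peak-height ratios). Includes a forward model of the trilayer unit cell
    and of FTIR responses used for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
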