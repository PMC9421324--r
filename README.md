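# lamellar

Neutron-diffraction and FTIR analysis of stratum corneum lipid model
membranes forming the ~12.6 nm long periodicity phase (LPP).

The extracellular lipid matrix of the skin's outermost layer is built from
ceramides, cholesterol and free fatty acids that crystallize into a lamellar
phase whose unit cell stacks three lipid layers. Localizing a selectively
deuterated ceramide chain inside that trilayer requires a chain of analyses:

1. **Reduction** — Bragg peaks of the 1D pattern I(q) are fitted with
   Pearson VII profiles; the lamellar law `q_n = 2*pi*n/d` indexes the orders
   and yields the repeat distance d, excluding the crystalline-CHOL
   (1.8 nm^-1) and impurity (1.2 nm^-1) reflections; amplitudes follow
   `|F_n| = sqrt(A_n * L * I_n)` with the oriented-sample Lorentz correction
   `L = q_n` and slab absorption factor `A_n`.
2. **Phasing** — the unit cell is centrosymmetric, so each `F_n` is real
   with an unknown sign. Measuring at 8/50/100% D2O makes the
   water-associated component of each order linear in the buffer contrast
   (exactly zero at the 8% null point); the slopes fix the water-profile
   signs (`- + - + - +` for the trilayer), and each sample's signs follow
   from the sign of its contrast line at 8%, flipped where the line crosses
   zero (giving `+ + - + - +` for perdeuterated-acyl samples).
3. **Reconstruction** — Fourier synthesis
   `rho(x) = F0 + 2 * sum F_n cos(2*pi*n*x/d)` gives the unit-cell SLD
   profile; the 100% − 8% difference is the water profile, and
   deuterated − protiated differences at 8% localize the labelled chains,
   placed on a relative-absolute scale by normalizing the fitted
   difference-peak area to the expected label scattering (Eq.-6 scaling).
4. **FTIR** — CH2/CD2 symmetric-stretch thermotropics give the
   ordered-disordered midpoint T_M; Lorentzian triplet fits of the
   scissoring bands give the orthorhombic splitting and the OR/MID
   peak-height ratio, compared across models by unpaired t tests.

A tested synthetic forward model of the trilayer unit cell (and of the FTIR
responses) generates every input and provides ground truth for
parameter-recovery validation.

## Worked example

```r
library(lamellar)

# protiated trilayer model and a terminally deuterated (d7) variant
m_prot <- trilayer_model()
m_d7   <- trilayer_model(labels = data.frame(center_nm = 4.2,
                                             sigma_nm = 0.6, amplitude = 0.5))

cfg <- sim_config(noise_fraction = 0.01, seed = 1)
mk  <- function(m) synthesize_contrast_series(m, cfg)$patterns

res <- run_diffraction_pipeline(
  list(prot = mk(m_prot), NSd7 = mk(m_d7)), reference = "prot")

res$prot$phase
#> Lamellar phase: d = 12.6 nm; 6 orders assigned; 2 peak(s) excluded
res$prot$water_assignment
#> Phase assignment (water basis): - + - + - +
res$prot$water_extrema
#>   position_nm    value relative_height  pair uncertainty_nm
#> 1   -6.300050 7.207368       1.0000000 FALSE    0.003225229
#> 2    2.154272 2.567751       0.5198347  TRUE    0.004194697
res$NSd7$label_extrema
#>   position_nm     value relative_height pair uncertainty_nm
#> 1    4.181664 0.7266993               1 TRUE     0.01006735
```

The water profile peaks at the head-group planes (±2.2 and ±6.3 nm from the
unit-cell centre, the boundary maximum reported at −6.3 ≡ +6.3 under
periodicity), and the d7 label difference profile localizes the terminal
sphingosine deuterons at ±4.2 nm — close to the all-trans prediction
`2.2 nm + 15 bonds x 0.125 nm ≈ 4.1 nm` from
`predict_chain_positions(bonds = 15, headgroup_position_nm = 2.2)`.

## Analysis workflow

The `analysis/` scripts run the full study pipeline and write tables under
`results/`:

```sh
Rscript analysis/01_simulate.R          # synthetic patterns, traces, spectra
Rscript analysis/02_reduce.R            # per-order |F_n| CSVs, d-spacing table
Rscript analysis/03_phase_reconstruct.R # phase signs, SLD/water/label profiles
Rscript analysis/04_ftir.R              # T_M table, scissoring table, t test
Rscript analysis/05_chain_geometry.R    # chain extents, composition shares
```

## Package layout

- `R/` — forward model, peak reduction, contrast phasing, SLD
  reconstruction, composition/chain geometry, FTIR analysis, pipeline
  orchestration and two-column text I/O.
- `vignettes/lpp-methods.Rmd` — the methods vignette: model assumptions,
  parameter choices, numerical decisions, limitations.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
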