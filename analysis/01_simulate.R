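#!/usr/bin/env Rscript
# Generate the synthetic study data: D2O/H2O contrast series of 1D
# diffraction patterns for the protiated LPP model and the three deuterated
# variants, plus FTIR thermotropic traces and scissoring spectra. Patterns
# are written as commented two-column text under results/synthetic/ with a
# JSON ground-truth sidecar per sample.

suppressPackageStartupMessages(library(lamellar))

out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 1L
cfg <- sim_config(noise_fraction = 0.01, seed = seed)

models <- list(
  `LPP_prot` = trilayer_model(),
  `LPP_NSd7` = trilayer_model(labels = data.frame(
    center_nm = 4.2, sigma_nm = 0.6, amplitude = 0.5)),
  `LPP_NSd47` = trilayer_model(labels = data.frame(
    center_nm = c(0, 6.3), sigma_nm = c(0.9, 0.6), amplitude = c(3, 0.8))),
  `LPP_NPd47` = trilayer_model(labels = data.frame(
    center_nm = c(0, 6.3), sigma_nm = c(0.9, 0.6), amplitude = c(2.9, 0.85)))
)

for (id in names(models)) {
  bundle <- synthesize_contrast_series(models[[id]], cfg)
  for (fr in names(bundle$patterns)) {
    p <- bundle$patterns[[fr]]
    attr(p, "sample_id") <- id
    write_two_column(p, file.path(out_dir, sprintf("%s_d2o%s.dat", id, fr)))
  }
  truth <- lapply(bundle$truth, function(s)
    list(n = s$n, F = s$F, F0 = attr(s, "F0")))
  jsonlite::write_json(
    list(model = unclass(models[[id]]), truth = truth),
    file.path(out_dir, sprintf("%s_truth.json", id)),
    auto_unbox = TRUE, digits = NA)
  cat(sprintf("%s: %d patterns, signs at 8%%: %s\n", id,
              length(bundle$patterns),
              paste(ifelse(bundle$truth[["8"]]$F > 0, "+", "-"),
                    collapse = " ")))
}

# FTIR: thermotropic traces (study midpoints) and scissoring replicates
tm_cfg <- list(
  `LPP_prot` = 71.2, `LPP_NSd47` = 71.4, `LPP_NPd47` = 68.0,
  `LPP_NSd47_DFFA24` = 66.9, `LPP_NPd47_DFFA24` = 68.5,
  `LPP_NSd47_NPd47_DFFA24` = 69.2)
thermo <- lapply(names(tm_cfg), function(id) {
  tr <- synthesize_thermo_trace(midpoints = c(37, tm_cfg[[id]]),
                                noise_sd = 0.1,
                                seed = seed + which(names(tm_cfg) == id))
  utils::write.csv(tr, file.path(out_dir, sprintf("%s_vsCH2_trace.csv", id)),
                   row.names = FALSE)
  tr
})
cat("wrote", length(thermo), "thermotropic traces\n")

sciss <- list(  # centers chosen to reproduce the study splittings
  `LPP_prot` = list(centers = c(1463, 1467, 1473.3), ratio = 3.1,
                    band = "dCH2", widths = c(1.2, 1.5, 1.2)),
  `LPP_NPd47_DFFA24` = list(centers = c(1086, 1088.5, 1091.4), ratio = 3.5,
                            band = "dCD2", widths = c(0.9, 1.1, 0.9)),
  `LPP_NSd47_DFFA24` = list(centers = c(1086, 1088.5, 1091.2), ratio = 3.1,
                            band = "dCD2", widths = c(0.9, 1.1, 0.9)))
k <- 100L
for (id in names(sciss)) {
  sc <- sciss[[id]]
  for (rep in 1:3) {
    sp <- synthesize_scissoring_spectrum(
      sc$centers, sc$widths, c(0.8, 0.79 / sc$ratio, 0.78),
      noise_sd = 0.004, seed = seed + k)
    k <- k + 1L
    attr(sp, "sample_id") <- id
    write_two_column(sp, file.path(out_dir,
                                   sprintf("%s_%s_rep%d.dat", id, sc$band,
                                           rep)))
  }
}
cat("wrote scissoring replicates for", length(sciss), "models\n")
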