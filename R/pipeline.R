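#' Per-order sign of the fitted contrast line at any fraction
#'
#' @param assignment A sample `phase_assignment` (from
#'   [assign_sample_phases()], whose diagnostics carry the fitted lines).
#' @param fraction Buffer D2O percentage.
#' @return Integer sign vector (+1/-1, NA where ambiguous).
#' @export
signs_at_fraction <- function(assignment, fraction) {
  stopifnot(inherits(assignment, "phase_assignment"))
  dg <- assignment$diagnostics
  if (is.null(dg$slope) || is.null(dg$F_at_8)) {
    stop("assignment carries no fitted lines (use a sample assignment)")
  }
  val <- dg$F_at_8 + dg$slope * (fraction - 8)
  out <- ifelse(is.na(assignment$signs), NA_integer_,
                as.integer(sign(val)))
  ifelse(out == 0L, NA_integer_, out)
}

#' Run the full diffraction pipeline on a set of contrast series
#'
#' For each sample: reduce every pattern (Pearson VII fits, order assignment,
#' Lorentz and absorption corrections), build the contrast series, assign
#' water and sample phase signs, reconstruct SLD profiles at every fraction,
#' form the water profile (100% minus 8%), and — for deuterated samples —
#' the label difference profile against the protiated reference at the 8%
#' null contrast, with located extrema. Every excluded peak, flipped sign and
#' ambiguous order is recorded in the result's `log`.
#'
#' @param samples Named list: sample id -> named list of
#'   [diffraction_pattern()]s keyed by D2O fraction (names like "8", "50",
#'   "100"), or file paths readable by [load_pattern()].
#' @param reference Id of the protiated reference sample (for label
#'   difference profiles); NULL disables differences.
#' @param n_max Highest diffraction order.
#' @param mu_per_mm,thickness_mm,wavelength_nm Absorption geometry (see
#'   [structure_factor_amplitudes()]).
#' @param F0 Mean SLD per sample: named numeric vector (or scalar) in
#'   1e-6 A^-2; default 0 (relative scale).
#' @param grid_n Reconstruction grid size.
#' @return List of class `diffraction_results`: per-sample list with
#'   `phase`, `sfs` (per fraction), `series`, `water_assignment`,
#'   `sample_assignment`, `profiles` (per fraction), `water_profile`,
#'   `water_extrema`, `label_profile`, `label_extrema`; plus `log`.
#' @export
run_diffraction_pipeline <- function(samples, reference = NULL, n_max = 6,
                                     mu_per_mm = 0, thickness_mm = 0.03,
                                     wavelength_nm = NULL, F0 = 0,
                                     grid_n = 1201) {
  stopifnot(is.list(samples), length(samples) >= 1,
            !is.null(names(samples)))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  res <- list()
  for (id in names(samples)) {
    pats <- samples[[id]]
    if (!is.list(pats) || is.null(names(pats))) {
      stop("sample '", id, "' must be a named list of patterns by fraction")
    }
    sfs_list <- list()
    phase <- NULL
    for (fr in names(pats)) {
      p <- pats[[fr]]
      if (is.character(p)) p <- load_pattern(p)
      attr(p, "d2o_fraction") <- as.numeric(fr)
      red <- reduce_pattern(p, n_max = n_max, mu_per_mm = mu_per_mm,
                            thickness_mm = thickness_mm,
                            wavelength_nm = wavelength_nm)
      for (k in seq_len(nrow(red$phase$excluded))) {
        say("%s @%s%%: excluded peak at q=%.3f nm^-1 (%s)", id, fr,
            red$phase$excluded$q[k], red$phase$excluded$reason[k])
      }
      sfs_list[[fr]] <- red$sfs
      phase <- red$phase
    }
    series <- build_contrast_series(sfs_list, sample_id = id)
    water <- assign_water_phases(series)
    for (k in which(water$diagnostics$ambiguous)) {
      say("%s: water sign of order %d ambiguous (%s)", id,
          water$diagnostics$order[k], water$diagnostics$reason[k])
    }
    samp <- assign_sample_phases(series, water)
    for (k in which(isTRUE(samp$diagnostics$flipped) |
                      samp$diagnostics$flipped %in% TRUE)) {
      say("%s: order %d sign flipped (line crosses zero at %.1f%% D2O)", id,
          samp$diagnostics$order[k], samp$diagnostics$crossing_fraction[k])
    }
    F0_id <- if (length(F0) > 1) unname(F0[id]) else unname(F0)
    if (is.na(F0_id)) F0_id <- 0
    profiles <- list()
    for (fr in names(sfs_list)) {
      sgn <- signs_at_fraction(samp, as.numeric(fr))
      sfs_signed <- sfs_list[[fr]]
      sfs_signed$F <- sfs_signed$amplitude * sgn[sfs_signed$n]
      keep <- !is.na(sfs_signed$F)
      if (!all(keep)) {
        say("%s @%s%%: dropping ambiguous order(s) %s from synthesis", id, fr,
            paste(sfs_signed$n[!keep], collapse = ","))
        sfs_signed <- sfs_signed[keep, ]
        attr(sfs_signed, "d_nm") <- attr(sfs_list[[fr]], "d_nm")
        attr(sfs_signed, "d2o_fraction") <- as.numeric(fr)
        class(sfs_signed) <- class(sfs_list[[fr]])
      }
      profiles[[fr]] <- fourier_synthesis(sfs_signed, F0 = F0_id,
                                          grid_n = grid_n)
    }
    water_profile <- NULL
    water_extrema <- NULL
    if (all(c("8", "100") %in% names(profiles))) {
      water_profile <- difference_profile(profiles[["100"]], profiles[["8"]])
      water_extrema <- locate_extrema(water_profile)
    }
    res[[id]] <- list(phase = phase, sfs = sfs_list, series = series,
                      water_assignment = water, sample_assignment = samp,
                      profiles = profiles, water_profile = water_profile,
                      water_extrema = water_extrema)
  }
  if (!is.null(reference)) {
    if (!reference %in% names(res)) stop("reference sample '", reference,
                                         "' not in manifest")
    ref8 <- res[[reference]]$profiles[["8"]]
    if (is.null(ref8)) stop("reference sample lacks the 8% fraction")
    for (id in setdiff(names(res), reference)) {
      p8 <- res[[id]]$profiles[["8"]]
      if (is.null(p8)) next
      lp <- difference_profile(p8, ref8)
      res[[id]]$label_profile <- lp
      res[[id]]$label_extrema <- locate_extrema(lp)
    }
  }
  structure(c(res, list(log = log)), class = "diffraction_results")
}

#' Run the FTIR analysis pipeline
#'
#' Produces the transition-temperature table (band position at 10 degC and
#' ordered-disordered midpoint T_M per sample), the scissoring table
#' (splitting and OR/MID ratio, mean and SD over replicates) and the
#' requested two-group comparisons of the OR/MID ratios.
#'
#' @param thermo Named list: sample id -> `thermo_trace` (see
#'   [track_band_position()] / [synthesize_thermo_trace()]).
#' @param scissoring Named list: sample id -> list with elements `spectra`
#'   (list of replicate [ftir_spectrum()]s) and `band` (`"dCH2"`/`"dCD2"`).
#' @param compare List of length-2 character vectors of sample ids whose
#'   OR/MID ratios are compared by unpaired t test.
#' @return List of class `ftir_results` with `tm_table`, `scissoring_table`,
#'   `ratios` (per-sample replicate ratios), `comparisons`.
#' @export
run_ftir_pipeline <- function(thermo = list(), scissoring = list(),
                              compare = list()) {
  if (length(thermo) == 0 && length(scissoring) == 0) {
    stop("empty manifest: provide thermotropic traces and/or scissoring ",
         "spectra")
  }
  tm_table <- NULL
  if (length(thermo) > 0) {
    rows <- lapply(names(thermo), function(id) {
      tr <- thermo[[id]]
      i10 <- which.min(abs(tr$temperature_C - 10))
      tm <- transition_midpoint(tr)
      data.frame(sample = id,
                 wavenumber_10C = tr$wavenumber[i10],
                 T_M_C = tm$T_M_C,
                 no_transition = tm$no_transition)
    })
    tm_table <- do.call(rbind, rows)
  }
  scissoring_table <- NULL
  ratios <- list()
  if (length(scissoring) > 0) {
    rows <- lapply(names(scissoring), function(id) {
      entry <- scissoring[[id]]
      fits <- lapply(entry$spectra, fit_scissoring_triplet, band = entry$band)
      sp <- vapply(fits, function(f) f$splitting_cm, numeric(1))
      ra <- vapply(fits, function(f) f$or_mid_ratio, numeric(1))
      ratios[[id]] <<- ra
      data.frame(sample = id, band = entry$band,
                 splitting_mean = mean(sp, na.rm = TRUE),
                 splitting_sd = stats::sd(sp[!is.na(sp)]),
                 ratio_mean = mean(ra, na.rm = TRUE),
                 ratio_sd = stats::sd(ra[!is.na(ra)]),
                 n = length(fits))
    })
    scissoring_table <- do.call(rbind, rows)
  }
  comparisons <- lapply(compare, function(pair) {
    stopifnot(length(pair) == 2)
    if (!all(pair %in% names(ratios))) {
      stop("comparison refers to unknown sample(s): ",
           paste(setdiff(pair, names(ratios)), collapse = ", "))
    }
    tt <- compare_peak_ratios(ratios[[pair[1]]], ratios[[pair[2]]])
    c(list(a = pair[1], b = pair[2]), tt)
  })
  structure(list(tm_table = tm_table, scissoring_table = scissoring_table,
                 ratios = ratios, comparisons = comparisons),
            class = "ftir_results")
}
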