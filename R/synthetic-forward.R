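#' Forward model of the centrosymmetric trilayer unit cell
#'
#' Builds a parametric scattering-length-density model of the ~12.6 nm
#' long-periodicity-phase unit cell: a flat hydrocarbon baseline, Gaussian
#' head-group bands mirrored about the cell centre, Gaussian deuterated-label
#' components, and a water term localized at the head-group planes whose
#' amplitude scales linearly with the D2O/H2O mixture contrast (zero at the
#' 8% null point, `water_amplitude` at 100% D2O). Every off-centre component
#' is mirrored, so the density is even in x by construction; components are
#' summed over periodic images so the density is d-periodic.
#'
#' @param repeat_distance_nm Lamellar repeat distance d (nm), > 0.
#' @param headgroup_positions_nm Distances of the head-group planes from the
#'   unit-cell centre (nm); defaults to the inner (2.2 nm) and boundary
#'   (6.3 nm) planes of the trilayer.
#' @param headgroup_sigma_nm Gaussian sigma of the head-group bands (nm).
#' @param headgroup_amplitude Peak SLD amplitude of each head-group band
#'   (1e-6/A^2 above baseline).
#' @param labels Data frame of deuterated-label components with columns
#'   `center_nm`, `sigma_nm`, `amplitude`; a zero-row data frame (default)
#'   means no label. Off-centre labels are mirrored.
#' @param water_positions_nm Positions of the water bands (defaults to the
#'   head-group positions).
#' @param water_sigma_nm Gaussian sigma of the water bands (nm).
#' @param water_amplitude Peak water SLD amplitude at 100% D2O.
#' @param baseline_sld Flat SLD level of the hydrocarbon matrix.
#' @return Object of class `trilayer_model`.
#' @export
#' @examples
#' m <- trilayer_model()
#' x <- seq(-6.3, 6.3, length.out = 5)
#' model_density(m, x, d2o_fraction = 100)
trilayer_model <- function(repeat_distance_nm = 12.6,
                           headgroup_positions_nm = c(2.2, 6.3),
                           headgroup_sigma_nm = 0.35,
                           headgroup_amplitude = 1.4,
                           labels = data.frame(center_nm = numeric(0),
                                               sigma_nm = numeric(0),
                                               amplitude = numeric(0)),
                           water_positions_nm = headgroup_positions_nm,
                           water_sigma_nm = 0.6,
                           water_amplitude = 2.5,
                           baseline_sld = -0.3) {
  d <- repeat_distance_nm
  if (!is.numeric(d) || length(d) != 1L || d <= 0) {
    stop("repeat_distance_nm must be a positive number")
  }
  stopifnot(is.data.frame(labels),
            all(c("center_nm", "sigma_nm", "amplitude") %in% names(labels)))
  pos_all <- c(headgroup_positions_nm, water_positions_nm, labels$center_nm)
  if (any(abs(pos_all) > d / 2 + 1e-9)) {
    stop("component position outside the unit cell: |x| must be <= d/2 = ",
         format(d / 2), " nm")
  }
  if (any(c(headgroup_sigma_nm, water_sigma_nm, labels$sigma_nm) <= 0)) {
    stop("Gaussian sigmas must be positive")
  }
  structure(
    list(
      repeat_distance_nm = d,
      headgroup_positions_nm = headgroup_positions_nm,
      headgroup_sigma_nm = headgroup_sigma_nm,
      headgroup_amplitude = headgroup_amplitude,
      labels = labels,
      water_positions_nm = water_positions_nm,
      water_sigma_nm = water_sigma_nm,
      water_amplitude = water_amplitude,
      baseline_sld = baseline_sld
    ),
    class = "trilayer_model"
  )
}

#' @export
print.trilayer_model <- function(x, ...) {
  cat("Trilayer unit-cell SLD model\n")
  cat("  d =", x$repeat_distance_nm, "nm; head groups at +/-",
      paste(x$headgroup_positions_nm, collapse = ", +/- "), "nm\n")
  cat("  labels:", nrow(x$labels), "component(s); water amplitude",
      x$water_amplitude, "at 100% D2O\n")
  invisible(x)
}

# sum of mirrored, d-periodic Gaussians with peak height `amp`
.mirrored_gaussians <- function(x, centers, sigmas, amps, d) {
  out <- numeric(length(x))
  for (i in seq_along(centers)) {
    cs <- if (abs(centers[i]) < 1e-12) centers[i] else c(-centers[i], centers[i])
    for (c0 in cs) {
      for (k in -1:1) {  # periodic images; sigmas << d so 3 images suffice
        out <- out + amps[i] * exp(-(x - c0 - k * d)^2 / (2 * sigmas[i]^2))
      }
    }
  }
  out
}

#' Evaluate the model SLD density
#'
#' @param model A [trilayer_model()].
#' @param x Positions in the unit cell (nm).
#' @param d2o_fraction D2O percentage of the hydration buffer; the water term
#'   is weighted by [water_contrast_weight()] (exactly zero at 8%).
#' @return SLD values (1e-6/A^2) at `x`.
#' @export
model_density <- function(model, x, d2o_fraction = 8) {
  stopifnot(inherits(model, "trilayer_model"))
  d <- model$repeat_distance_nm
  rho <- rep(model$baseline_sld, length(x))
  hp <- model$headgroup_positions_nm
  rho <- rho + .mirrored_gaussians(
    x, hp, rep(model$headgroup_sigma_nm, length(hp)),
    rep(model$headgroup_amplitude, length(hp)), d)
  if (nrow(model$labels) > 0) {
    rho <- rho + .mirrored_gaussians(
      x, model$labels$center_nm, model$labels$sigma_nm,
      model$labels$amplitude, d)
  }
  w <- water_contrast_weight(d2o_fraction)
  if (model$water_amplitude != 0 && abs(w) > 0) {
    wp <- model$water_positions_nm
    rho <- rho + w * .mirrored_gaussians(
      x, wp, rep(model$water_sigma_nm, length(wp)),
      rep(model$water_amplitude, length(wp)), d)
  }
  rho
}

#' Construct a structure-factor set
#'
#' Container for per-order structure factors of a lamellar phase.
#'
#' @param n Diffraction orders.
#' @param F Signed structure factors (or unsigned amplitudes with `sign` NA).
#' @param d_nm Repeat distance.
#' @param d2o_fraction D2O percentage of the buffer.
#' @param F0 Mean SLD level (zeroth coefficient), if known.
#' @param extra Optional data frame columns (corrections, diagnostics).
#' @return Object of class `structure_factor_set`: a data frame with columns
#'   `n`, `q_nm` and either signed `F` or `amplitude`, with attributes
#'   `d_nm`, `d2o_fraction`, `F0`.
#' @export
structure_factor_set <- function(n, F, d_nm, d2o_fraction = NA_real_,
                                 F0 = NA_real_, extra = NULL) {
  stopifnot(length(n) == length(F), d_nm > 0)
  df <- data.frame(n = n, q_nm = 2 * pi * n / d_nm, F = F)
  df$amplitude <- abs(F)
  if (!is.null(extra)) df <- cbind(df, extra)
  structure(df, class = c("structure_factor_set", "data.frame"),
            d_nm = d_nm, d2o_fraction = d2o_fraction, F0 = F0)
}

#' Fourier coefficients of a trilayer model
#'
#' Signed structure factors F_n = (2/d) * integral of rho(x) cos(2 pi n x / d)
#' over one unit cell, and F0 = mean of rho, computed by Simpson quadrature on
#' a dense grid.
#'
#' @param model A [trilayer_model()].
#' @param d2o_fraction Buffer D2O percentage.
#' @param n_orders Number of diffraction orders.
#' @param n_quad Quadrature points (odd; default 4097).
#' @return A [structure_factor_set()] with signed `F` and attribute `F0`.
#' @export
profile_to_structure_factors <- function(model, d2o_fraction = 8,
                                         n_orders = 6, n_quad = 4097) {
  stopifnot(inherits(model, "trilayer_model"), n_orders >= 1)
  d <- model$repeat_distance_nm
  if (n_quad %% 2 == 0) n_quad <- n_quad + 1
  x <- seq(-d / 2, d / 2, length.out = n_quad)
  rho <- model_density(model, x, d2o_fraction)
  if (any(!is.finite(rho))) stop("model density is not finite")
  h <- x[2] - x[1]
  wts <- c(1, rep(c(4, 2), (n_quad - 3) / 2), 4, 1) * h / 3
  F0 <- sum(wts * rho) / d
  Fn <- vapply(seq_len(n_orders), function(n) {
    2 / d * sum(wts * rho * cos(2 * pi * n * x / d))
  }, numeric(1))
  structure_factor_set(seq_len(n_orders), Fn, d_nm = d,
                       d2o_fraction = d2o_fraction, F0 = F0)
}

#' Simulation configuration for synthetic diffraction patterns
#'
#' @param d2o_fractions Buffer D2O percentages (default 8, 50, 100 — the
#'   contrast-variation protocol).
#' @param n_orders Number of lamellar orders to synthesize (default 6).
#' @param noise_fraction Relative (multiplicative Gaussian) intensity noise.
#' @param seed Integer seed; all pattern noise flows from it.
#' @param extra_peaks Data frame (`q_nm`, `intensity`) of non-lamellar
#'   reflections; defaults to the phase-separated crystalline CHOL reflection
#'   at 1.8 nm^-1 and the minor impurity phase at 1.2 nm^-1.
#' @param q_range,q_step Grid of the synthetic pattern (nm^-1).
#' @param peak_width,pearson_m Pearson VII width and shape exponent shared
#'   with the reduction module.
#' @param background Constant background level (counts).
#' @param mu_per_mm,thickness_mm,wavelength_nm Absorption geometry used to
#'   pre-distort intensities (so reduction must undo it); `mu_per_mm = 0`
#'   disables absorption.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(d2o_fractions = c(8, 50, 100),
                       n_orders = 6,
                       noise_fraction = 0,
                       seed = 1L,
                       extra_peaks = data.frame(q_nm = c(1.2, 1.8),
                                                intensity = c(0.05, 0.6)),
                       q_range = c(0.3, 3.35),
                       q_step = 0.0015,
                       peak_width = 0.012,
                       pearson_m = 3,
                       background = 0.02,
                       mu_per_mm = 0,
                       thickness_mm = 0.03,
                       wavelength_nm = 0.3) {
  stopifnot(all(d2o_fractions >= 0 & d2o_fractions <= 100),
            n_orders >= 1, noise_fraction >= 0,
            q_range[1] > 0, q_range[2] > q_range[1], q_step > 0)
  structure(list(
    d2o_fractions = d2o_fractions, n_orders = n_orders,
    noise_fraction = noise_fraction, seed = as.integer(seed),
    extra_peaks = extra_peaks, q_range = q_range, q_step = q_step,
    peak_width = peak_width, pearson_m = pearson_m, background = background,
    mu_per_mm = mu_per_mm, thickness_mm = thickness_mm,
    wavelength_nm = wavelength_nm
  ), class = "sim_config")
}

#' Synthesize a 1D diffraction pattern from structure factors
#'
#' Places a Pearson VII peak at each lamellar position q_n = 2 pi n / d with
#' integrated area I_n = F_n^2 / (A_n q_n), so that peak reduction (Lorentz
#' correction L = q, absorption correction A_n) recovers |F_n| exactly in the
#' noise-free case. Configured extra (non-lamellar) reflections and a
#' constant background are added, then multiplicative Gaussian noise from the
#' configured seed.
#'
#' @param sfs A [structure_factor_set()] with signed or unsigned `F`.
#' @param d Repeat distance (nm); defaults to the set's own.
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `diffraction_pattern` (see [diffraction_pattern()]).
#' @export
synthesize_pattern <- function(sfs, d = attr(sfs, "d_nm"), config = sim_config(),
                               seed = NULL) {
  stopifnot(inherits(sfs, "structure_factor_set"), d > 0,
            inherits(config, "sim_config"))
  q <- seq(config$q_range[1], config$q_range[2], by = config$q_step)
  if (length(q) < 10) stop("empty or too-narrow q range")
  intensity <- rep(config$background, length(q))
  for (i in seq_len(nrow(sfs))) {
    qn <- 2 * pi * sfs$n[i] / d
    if (qn > max(q) || qn < min(q)) next
    A_n <- .absorption_at_q(qn, config)
    area <- sfs$F[i]^2 / (A_n * qn)
    intensity <- intensity +
      pearson7(q, .pearson7_height(area, config$peak_width, config$pearson_m),
               qn, config$peak_width, config$pearson_m)
  }
  ep <- config$extra_peaks
  if (!is.null(ep) && nrow(ep) > 0) {
    for (i in seq_len(nrow(ep))) {
      intensity <- intensity +
        pearson7(q, .pearson7_height(ep$intensity[i], config$peak_width,
                                     config$pearson_m),
                 ep$q_nm[i], config$peak_width, config$pearson_m)
    }
  }
  if (config$noise_fraction > 0) {
    set.seed(if (is.null(seed)) config$seed else seed)
    intensity <- intensity *
      (1 + config$noise_fraction * stats::rnorm(length(q)))
    intensity <- pmax(intensity, 0)
  }
  diffraction_pattern(q, intensity,
                      sample_id = "synthetic",
                      d2o_fraction = attr(sfs, "d2o_fraction"))
}

# absorption correction at scattering vector q for a sim_config
.absorption_at_q <- function(q, config) {
  if (config$mu_per_mm <= 0) return(1)
  theta <- asin(q * config$wavelength_nm / (4 * pi))
  absorption_correction(theta, config$mu_per_mm, config$thickness_mm)
}

#' Synthesize a D2O/H2O contrast series of patterns
#'
#' One pattern per configured D2O fraction, all derived from the same
#' trilayer model; the signed ground-truth structure factors per fraction are
#' retained for parameter-recovery tests. Noise seeds are derived from the
#' config seed, one per fraction.
#'
#' @param model A [trilayer_model()].
#' @param config A [sim_config()] with at least two distinct fractions.
#' @return List of class `contrast_bundle` with elements `patterns` (named by
#'   fraction), `truth` (list of signed [structure_factor_set()]s), `model`,
#'   `config`.
#' @export
synthesize_contrast_series <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "trilayer_model"), inherits(config, "sim_config"))
  fr <- unique(config$d2o_fractions)
  if (length(fr) < 2) {
    stop("need at least two distinct D2O fractions for a contrast series")
  }
  patterns <- list()
  truth <- list()
  for (i in seq_along(fr)) {
    sfs <- profile_to_structure_factors(model, fr[i], config$n_orders)
    truth[[as.character(fr[i])]] <- sfs
    patterns[[as.character(fr[i])]] <-
      synthesize_pattern(sfs, model$repeat_distance_nm, config,
                         seed = config$seed + 1000L * i)
  }
  structure(list(patterns = patterns, truth = truth, model = model,
                 config = config),
            class = "contrast_bundle")
}

#' Synthesize a thermotropic band-position trace
#'
#' Double-sigmoid wavenumber-versus-temperature curve emulating the CH2/CD2
#' symmetric-stretching response of an LPP lipid model: a small
#' orthorhombic-to-hexagonal step and a larger ordered-to-disordered
#' (hexagonal-to-liquid) step with known midpoints.
#'
#' @param temperatures Strictly increasing temperature grid (deg C).
#' @param base Low-temperature plateau wavenumber (cm^-1).
#' @param step_heights Heights of the two sigmoid steps (cm^-1);
#'   defaults to ~1 (orthorhombic-hexagonal) and 3.5 (order-disorder,
#'   2850.5 to 2854).
#' @param midpoints Transition midpoints (deg C); defaults 37 and 71.2.
#' @param widths Sigmoid scale parameters (deg C).
#' @param noise_sd Additive Gaussian noise on the wavenumber (cm^-1).
#' @param seed Seed for the noise.
#' @param band Band label (`"vsCH2"` or `"vsCD2"`).
#' @return Object of class `thermo_trace`: data frame `temperature_C`,
#'   `wavenumber` with attributes `band` and `truth` (the generating
#'   parameters).
#' @export
synthesize_thermo_trace <- function(temperatures = 10:90,
                                    base = 2849,
                                    step_heights = c(1, 3.5),
                                    midpoints = c(37, 71.2),
                                    widths = c(1, 1.5),
                                    noise_sd = 0, seed = 1L,
                                    band = "vsCH2") {
  if (any(diff(temperatures) <= 0)) {
    stop("temperature grid must be strictly increasing")
  }
  stopifnot(length(step_heights) == length(midpoints),
            length(widths) == length(midpoints))
  w <- rep(base, length(temperatures))
  for (i in seq_along(midpoints)) {
    w <- w + step_heights[i] / (1 + exp(-(temperatures - midpoints[i]) / widths[i]))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    w <- w + stats::rnorm(length(w), sd = noise_sd)
  }
  structure(data.frame(temperature_C = temperatures, wavenumber = w),
            class = c("thermo_trace", "data.frame"), band = band,
            truth = list(base = base, step_heights = step_heights,
                         midpoints = midpoints, widths = widths))
}

#' Synthesize a scissoring-band spectrum
#'
#' Sum of one to three Lorentzian components plus a linear baseline and
#' optional additive noise, emulating the CH2 (1,462-1,473 cm^-1) or CD2
#' (1,085-1,095 cm^-1) scissoring region of an orthorhombically packed lipid
#' model.
#'
#' @param centers Component centres (cm^-1), inside `window`.
#' @param widths Lorentzian half-widths at half maximum (cm^-1).
#' @param heights Component peak heights.
#' @param window Wavenumber window c(lo, hi); defaults to the CH2 scissoring
#'   band when the centres lie above 1400, else the CD2 band.
#' @param step Sampling step (cm^-1).
#' @param baseline Constant baseline absorbance.
#' @param noise_sd Additive Gaussian noise (absorbance units).
#' @param seed Seed for the noise.
#' @return Object of class `ftir_spectrum`: data frame `wavenumber`,
#'   `absorbance`, with attribute `truth`.
#' @export
synthesize_scissoring_spectrum <- function(centers, widths, heights,
                                           window = NULL, step = 0.1,
                                           baseline = 0.02,
                                           noise_sd = 0, seed = 1L) {
  stopifnot(length(centers) >= 1, length(centers) <= 3,
            length(widths) == length(centers),
            length(heights) == length(centers),
            all(widths > 0))
  if (is.null(window)) {
    window <- if (mean(centers) > 1400) c(1455, 1480) else c(1080, 1100)
  }
  if (any(centers < window[1] | centers > window[2])) {
    stop("component centres must lie inside the band window [",
         window[1], ", ", window[2], "] cm^-1")
  }
  x <- seq(window[1], window[2], by = step)
  y <- rep(baseline, length(x))
  for (i in seq_along(centers)) {
    y <- y + heights[i] * widths[i]^2 / ((x - centers[i])^2 + widths[i]^2)
  }
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  structure(data.frame(wavenumber = x, absorbance = y),
            class = c("ftir_spectrum", "data.frame"),
            truth = list(centers = centers, widths = widths,
                         heights = heights, baseline = baseline))
}
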