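#' Construct an FTIR spectrum
#'
#' @param wavenumber Wavenumber grid (cm^-1), strictly increasing.
#' @param absorbance Absorbance values.
#' @param temperature_C Measurement temperature.
#' @param sample_id Sample identifier.
#' @return Object of class `ftir_spectrum`.
#' @export
ftir_spectrum <- function(wavenumber, absorbance, temperature_C = NA_real_,
                          sample_id = NA_character_) {
  if (length(wavenumber) != length(absorbance)) {
    stop("wavenumber and absorbance lengths differ")
  }
  if (any(diff(wavenumber) <= 0)) stop("wavenumber must be strictly increasing")
  structure(data.frame(wavenumber = wavenumber, absorbance = absorbance),
            class = c("ftir_spectrum", "data.frame"),
            temperature_C = temperature_C, sample_id = sample_id)
}

#' Canonical scissoring-band definitions
#'
#' Band windows and canonical component positions of the CH2 and CD2
#' scissoring triplets: the two orthorhombic correlation-field components and
#' the central (hexagonal / isolated-chain) component.
#'
#' @param band `"dCH2"` (1,462-1,473 cm^-1) or `"dCD2"` (1,085-1,095 cm^-1).
#' @return List with `window` and `centers`.
#' @export
scissoring_band <- function(band = c("dCH2", "dCD2")) {
  band <- match.arg(band)
  if (band == "dCH2") {
    list(window = c(1455, 1480), centers = c(1463, 1467, 1473))
  } else {
    list(window = c(1080, 1100), centers = c(1086, 1088.5, 1091))
  }
}

#' Fourier self-deconvolution of a band spectrum
#'
#' Lorentzian band narrowing in the Fourier domain: the interferogram of the
#' (linear-trend-removed) spectrum is multiplied by
#' `exp(2 pi gamma (1 - 1/K) |t|)`, which turns an assumed Lorentzian line of
#' half-width (HWHM) `gamma` into one of half-width `gamma / K`. With
#' enhancement `K = 1` the spectrum is returned unchanged. Noise is amplified
#' monotonically with `K` — the classical resolution/noise trade-off of
#' self-deconvolution.
#'
#' Beyond the Fourier lag where the deconvolved interferogram of a true
#' Lorentzian would have decayed below `noise_cut`, the filter is zeroed:
#' without this cutoff the exponential gain amplifies floating-point and
#' measurement noise without bound. At `K = 1` no filtering is applied and
#' the output equals the input exactly.
#'
#' @param spectrum An [ftir_spectrum()] on a uniform wavenumber grid.
#' @param half_width Assumed Lorentzian half-width gamma (cm^-1; default 4).
#' @param enhancement Band-narrowing factor K >= 1 (default 1.4).
#' @param noise_cut Relative interferogram level below which the filter is
#'   truncated (default 1e-4).
#' @return The deconvolved [ftir_spectrum()] on the input grid.
#' @export
self_deconvolve <- function(spectrum, half_width = 4, enhancement = 1.4,
                            noise_cut = 1e-4) {
  stopifnot(inherits(spectrum, "ftir_spectrum"), half_width > 0,
            enhancement >= 1)
  x <- spectrum$wavenumber
  dx <- diff(x)
  if (max(dx) - min(dx) > 1e-6 * mean(dx)) {
    stop("non-uniform wavenumber grid; resample before deconvolution")
  }
  y <- spectrum$absorbance
  n <- length(y)
  # remove the chord between the endpoints so the signal is near-periodic
  chord <- y[1] + (y[n] - y[1]) * (x - x[1]) / (x[n] - x[1])
  yc <- y - chord
  ft <- stats::fft(yc)
  k <- seq_len(n) - 1
  t_cm <- pmin(k, n - k) / (n * mean(dx))  # conjugate variable |t| in cm
  gain <- exp(2 * pi * half_width * (1 - 1 / enhancement) * t_cm)
  if (enhancement > 1) {
    # truncate with a cosine roll-off where a true Lorentzian interferogram
    # would have decayed below noise_cut, to bound noise amplification
    t_cut <- enhancement * log(1 / noise_cut) / (2 * pi * half_width)
    roll <- t_cm > 0.5 * t_cut & t_cm <= t_cut
    gain[roll] <- gain[roll] *
      0.5 * (1 + cos(pi * (t_cm[roll] - 0.5 * t_cut) / (0.5 * t_cut)))
    gain[t_cm > t_cut] <- 0
  }
  out <- Re(stats::fft(ft * gain, inverse = TRUE)) / n + chord
  ftir_spectrum(x, out, temperature_C = attr(spectrum, "temperature_C"),
                sample_id = attr(spectrum, "sample_id"))
}

# peak position in a window: tallest interior maximum + parabolic refinement
.window_peak_position <- function(x, y, window) {
  sel <- which(x >= window[1] & x <= window[2])
  if (length(sel) < 3) return(NA_real_)
  xs <- x[sel]; ys <- y[sel]
  m <- length(ys)
  interior <- 2:(m - 1)
  is_max <- ys[interior] > ys[interior - 1] & ys[interior] >= ys[interior + 1]
  if (!any(is_max)) return(NA_real_)
  cand <- interior[is_max]
  i <- cand[which.max(ys[cand])]
  denom <- ys[i - 1] - 2 * ys[i] + ys[i + 1]
  delta <- if (denom < 0) 0.5 * (ys[i - 1] - ys[i + 1]) / denom else 0
  xs[i] + max(min(delta, 0.5), -0.5) * (xs[2] - xs[1])
}

#' Track a band position across a temperature series
#'
#' Per temperature, the band position is the tallest local maximum inside the
#' band window, refined by three-point parabolic interpolation. Temperatures
#' without an interior maximum are flagged missing (NA) rather than dropped.
#'
#' @param spectra List of [ftir_spectrum()]s, one per temperature (the
#'   temperature is read from each spectrum's attribute unless `temperatures`
#'   is given).
#' @param band_window c(lo, hi) wavenumber window, e.g. c(2845, 2855) for the
#'   CH2 symmetric stretch or c(2080, 2100) for the CD2 symmetric stretch.
#' @param temperatures Optional temperature vector overriding the attributes.
#' @param band Band label stored on the trace.
#' @return A `thermo_trace` (data frame `temperature_C`, `wavenumber`).
#' @export
track_band_position <- function(spectra, band_window, temperatures = NULL,
                                band = "vsCH2") {
  stopifnot(is.list(spectra), length(spectra) >= 1)
  if (is.null(temperatures)) {
    temperatures <- vapply(spectra, function(s) attr(s, "temperature_C"),
                           numeric(1))
  }
  if (any(is.na(temperatures))) stop("temperatures unknown for some spectra")
  ord <- order(temperatures)
  pos <- vapply(spectra[ord], function(s) {
    .window_peak_position(s$wavenumber, s$absorbance, band_window)
  }, numeric(1))
  structure(data.frame(temperature_C = temperatures[ord], wavenumber = pos),
            class = c("thermo_trace", "data.frame"), band = band,
            truth = NULL)
}

#' Midpoint temperature of the ordered-disordered transition
#'
#' Plateau-line-plateau estimate of the transition midpoint T_M: the largest
#' wavenumber step of the (lightly smoothed) trace is located via its maximum
#' slope; the plateaus flanking the step are estimated from the adjacent
#' quasi-flat segments; a linear regression through the central part of the
#' rise (25-75% of the step) is intersected with the mid-level between the
#' plateaus. For a sigmoidal step this reproduces the generating midpoint
#' exactly by symmetry.
#'
#' @param trace A `thermo_trace`.
#' @param min_range Minimum trace range (cm^-1) for a transition to be
#'   declared (default 0.3); below it the result reports no transition.
#' @param slope_frac Fraction of the peak slope delimiting the transition
#'   region (default 0.25).
#' @return Object of class `transition_result`: list with `T_M_C`,
#'   `plateau_low`, `plateau_high`, `no_transition`, `fit` (slope/intercept
#'   of the transition line).
#' @export
transition_midpoint <- function(trace, min_range = 0.3, slope_frac = 0.25) {
  stopifnot(inherits(trace, "thermo_trace"))
  ok <- is.finite(trace$wavenumber)
  tt <- trace$temperature_C[ok]
  w <- trace$wavenumber[ok]
  n <- length(w)
  if (n < 5) stop("trace too short for transition fitting")
  if (max(w) - min(w) < min_range) {
    return(structure(list(T_M_C = NA_real_, plateau_low = NA_real_,
                          plateau_high = NA_real_, no_transition = TRUE,
                          fit = NULL),
                     class = "transition_result"))
  }
  ws <- stats::filter(w, rep(1 / 3, 3), sides = 2)
  ws[is.na(ws)] <- w[is.na(ws)]
  ws <- as.numeric(ws)
  slope <- c(NA, (ws[3:n] - ws[1:(n - 2)]) / (tt[3:n] - tt[1:(n - 2)]), NA)
  i0 <- which.max(abs(slope))
  smax <- abs(slope[i0])
  inregion <- abs(slope) >= slope_frac * smax & !is.na(slope)
  lo_end <- i0
  while (lo_end > 1 && isTRUE(inregion[lo_end - 1])) lo_end <- lo_end - 1
  hi_end <- i0
  while (hi_end < n && isTRUE(inregion[hi_end + 1])) hi_end <- hi_end + 1
  pre <- max(1, lo_end - 8):(max(1, lo_end - 1))
  post <- (min(n, hi_end + 1)):min(n, hi_end + 8)
  plateau_low <- stats::median(ws[pre])
  plateau_high <- stats::median(ws[post])
  if (plateau_high < plateau_low) {  # falling step: swap roles
    tmp <- plateau_low; plateau_low <- plateau_high; plateau_high <- tmp
  }
  delta <- plateau_high - plateau_low
  core <- which(w > plateau_low + 0.25 * delta &
                  w < plateau_low + 0.75 * delta &
                  seq_len(n) >= lo_end - 1 & seq_len(n) <= hi_end + 1)
  if (length(core) < 2) core <- unique(pmax(1, pmin(n, (i0 - 1):(i0 + 1))))
  fit <- .ols_line(tt[core], w[core])
  mid <- (plateau_low + plateau_high) / 2
  structure(list(
    T_M_C = (mid - fit$intercept) / fit$slope,
    plateau_low = plateau_low, plateau_high = plateau_high,
    no_transition = FALSE,
    fit = list(slope = fit$slope, intercept = fit$intercept,
               r_squared = fit$r_squared, n_points = length(core))
  ), class = "transition_result")
}

#' @export
print.transition_result <- function(x, ...) {
  if (x$no_transition) {
    cat("No ordered-disordered transition detected\n")
  } else {
    cat("T_M =", format(x$T_M_C, digits = 4), "degC (plateaus",
        format(x$plateau_low, digits = 6), "->",
        format(x$plateau_high, digits = 6), "cm^-1)\n")
  }
  invisible(x)
}

#' Fit the scissoring triplet with three Lorentzians
#'
#' Least-squares fit of three Lorentzian components plus a linear baseline to
#' a scissoring band: the two orthorhombic correlation-field components and
#' the central component. Component centres are seeded at the band's
#' canonical positions with bounded drift (+/- 2 cm^-1) to prevent
#' component-swap degeneracy. The splitting is the distance between the outer
#' component centres; the OR/MID ratio is the mean height of the outer
#' (orthorhombic) components divided by the central component's height. If
#' the fit collapses to fewer than three distinguishable components the
#' splitting is reported undefined with a reason.
#'
#' @param spectrum An [ftir_spectrum()] covering the band window.
#' @param band `"dCH2"` or `"dCD2"` (see [scissoring_band()]).
#' @param deconvolve Apply [self_deconvolve()] before fitting (default FALSE:
#'   the raw band is fitted).
#' @param max_shift Allowed centre drift from the canonical positions
#'   (cm^-1).
#' @return Object of class `scissoring_fit`: list with `components` (data
#'   frame `center`, `width`, `height`), `splitting_cm`, `or_mid_ratio`,
#'   `undefined` (logical), `reason`, `band`, `rmse`.
#' @export
fit_scissoring_triplet <- function(spectrum, band = c("dCH2", "dCD2"),
                                   deconvolve = FALSE, max_shift = 2) {
  band <- match.arg(band)
  bd <- scissoring_band(band)
  stopifnot(inherits(spectrum, "ftir_spectrum"))
  if (deconvolve) spectrum <- self_deconvolve(spectrum)
  sel <- spectrum$wavenumber >= bd$window[1] &
    spectrum$wavenumber <= bd$window[2]
  if (sum(sel) < 12) stop("band window absent from spectrum")
  df <- data.frame(x = spectrum$wavenumber[sel], y = spectrum$absorbance[sel])
  c0 <- bd$centers
  h0 <- max(df$y) - min(df$y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ h1 * w1^2 / ((x - c1)^2 + w1^2) +
        h2 * w2^2 / ((x - c2)^2 + w2^2) +
        h3 * w3^2 / ((x - c3)^2 + w3^2) + a + b * (x - mean(x)),
      data = df,
      start = list(h1 = h0, h2 = h0 / 3, h3 = h0, c1 = c0[1], c2 = c0[2],
                   c3 = c0[3], w1 = 1, w2 = 1, w3 = 1,
                   a = min(df$y), b = 0),
      lower = c(0, 0, 0, c0 - max_shift, 0.2, 0.2, 0.2, -Inf, -Inf),
      upper = c(Inf, Inf, Inf, c0 + max_shift, 6, 6, 6, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(components = NULL, splitting_cm = NA_real_,
                          or_mid_ratio = NA_real_, undefined = TRUE,
                          reason = "fit did not converge", band = band,
                          rmse = NA_real_),
                     class = "scissoring_fit"))
  }
  p <- stats::coef(fit)
  comp <- data.frame(center = c(p[["c1"]], p[["c2"]], p[["c3"]]),
                     width = c(p[["w1"]], p[["w2"]], p[["w3"]]),
                     height = c(p[["h1"]], p[["h2"]], p[["h3"]]))
  comp <- comp[order(comp$center), ]
  rownames(comp) <- NULL
  rmse <- sqrt(mean(stats::resid(fit)^2))
  undef <- FALSE
  reason <- ""
  if (any(comp$height < 0.02 * max(comp$height))) {
    undef <- TRUE
    reason <- "fewer than 3 distinguishable components (vanishing height)"
  } else if (min(diff(comp$center)) < 1) {
    undef <- TRUE
    reason <- "component centres merged (< 1 cm^-1 apart)"
  }
  structure(list(
    components = comp,
    splitting_cm = if (undef) NA_real_ else comp$center[3] - comp$center[1],
    or_mid_ratio = if (undef || comp$height[2] <= 0) NA_real_ else
      mean(comp$height[c(1, 3)]) / comp$height[2],
    undefined = undef, reason = reason, band = band, rmse = rmse
  ), class = "scissoring_fit")
}

#' @export
print.scissoring_fit <- function(x, ...) {
  if (x$undefined) {
    cat("Scissoring fit (", x$band, "): splitting undefined — ", x$reason,
        "\n", sep = "")
  } else {
    cat("Scissoring fit (", x$band, "): splitting ",
        format(x$splitting_cm, digits = 4), " cm^-1, OR/MID ratio ",
        format(x$or_mid_ratio, digits = 3), "\n", sep = "")
  }
  invisible(x)
}

#' Unpaired t test of peak-height ratios between two groups
#'
#' Two-sided, equal-variance (pooled) unpaired t test, with significance
#' declared at P < 0.05. Degenerate zero-variance groups use the convention
#' P = 1 for equal means.
#'
#' @param group_a,group_b Numeric vectors of per-sample OR/MID ratios
#'   (each n >= 2).
#' @return List with `t`, `df`, `p_value`, `significant`, `mean_a`, `mean_b`.
#' @export
compare_peak_ratios <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (stats::sd(group_a) == 0 && stats::sd(group_b) == 0) {
    eq <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(list(t = if (eq) 0 else Inf,
                df = length(group_a) + length(group_b) - 2,
                p_value = if (eq) 1 else 0, significant = !eq,
                mean_a = mean(group_a), mean_b = mean(group_b)))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, significant = ht$p.value < 0.05,
       mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Unpaired t test from group summary statistics
#'
#' Closed-form pooled-variance t test from means, standard deviations and
#' sample sizes — the form needed when only a table of group summaries is
#' available.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b Group summaries.
#' @return List with `t`, `df`, `p_value`, `significant`.
#' @export
#' @examples
#' t_test_from_summary(3.5, 0.1, 3, 3.1, 0.2, 3)  # t ~ 3.1, P < 0.05
t_test_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df
  t <- (mean_a - mean_b) / sqrt(sp2 * (1 / n_a + 1 / n_b))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p_value = p, significant = p < 0.05)
}
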