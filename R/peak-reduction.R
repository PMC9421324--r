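#' Construct a 1D diffraction pattern
#'
#' @param q Scattering vector (nm^-1), strictly increasing.
#' @param intensity Counts, finite, same length as `q`.
#' @param sample_id Sample identifier.
#' @param d2o_fraction D2O percentage of the hydration buffer.
#' @param temperature_C Measurement temperature.
#' @return Object of class `diffraction_pattern` (a data frame `q`,
#'   `intensity` with metadata attributes).
#' @export
diffraction_pattern <- function(q, intensity, sample_id = NA_character_,
                                d2o_fraction = NA_real_,
                                temperature_C = NA_real_) {
  if (length(q) != length(intensity)) stop("q and intensity lengths differ")
  if (any(!is.finite(q)) || any(!is.finite(intensity))) {
    stop("q and intensity must be finite (no NaN/NA)")
  }
  if (any(diff(q) <= 0)) stop("non-monotone q: q must be strictly increasing")
  structure(data.frame(q = q, intensity = intensity),
            class = c("diffraction_pattern", "data.frame"),
            sample_id = sample_id, d2o_fraction = d2o_fraction,
            temperature_C = temperature_C)
}

#' Scattering vector from scattering angle
#'
#' q = 4 pi sin(theta) / lambda with theta half the scattering angle 2 theta.
#'
#' @param two_theta_deg Scattering angle 2 theta in degrees, in \[0, 180).
#' @param wavelength_nm Neutron wavelength (nm), > 0.
#' @return q in nm^-1.
#' @export
#' @examples
#' q_from_angle(5, 0.25)  # about 2.19 nm^-1
q_from_angle <- function(two_theta_deg, wavelength_nm) {
  if (any(wavelength_nm <= 0)) stop("wavelength must be positive")
  if (any(two_theta_deg < 0 | two_theta_deg >= 180)) {
    stop("2theta must be in [0, 180) degrees")
  }
  theta <- two_theta_deg / 2 * pi / 180
  4 * pi * sin(theta) / wavelength_nm
}

#' Lipid film thickness from sprayed mass
#'
#' thickness = mass / (density x area), converted to mm. For the 10 mg film
#' sprayed over 1.2 x 3.8 cm^2 used for oriented lamellar samples this gives
#' a few hundredths of a millimetre.
#'
#' @param mass_mg Sprayed lipid mass (mg).
#' @param area_cm2 Substrate area (cm^2).
#' @param density_g_per_cm3 Lipid mass density (g/cm^3).
#' @return Film thickness in mm.
#' @export
#' @examples
#' estimate_film_thickness(10, 10, 1.0)   # 0.01 mm
estimate_film_thickness <- function(mass_mg, area_cm2, density_g_per_cm3) {
  if (any(mass_mg <= 0) || any(area_cm2 <= 0) || any(density_g_per_cm3 <= 0)) {
    stop("mass, area and density must all be positive")
  }
  # mg/(g cm^-3 * cm^2) = 1e-3 cm = 1e-2 mm
  mass_mg / (density_g_per_cm3 * area_cm2) * 1e-2
}

#' Pearson VII peak profile
#'
#' `height * (1 + ((x - center)/width)^2 * (2^(1/m) - 1))^(-m)`: the common
#' parametrization in which `width` is the half-width at half maximum for
#' every shape exponent `m` (Lorentzian at m = 1, Gaussian as m -> Inf).
#'
#' @param x Abscissa.
#' @param height Peak height.
#' @param center Peak centre.
#' @param width Half-width at half maximum, > 0.
#' @param m Shape exponent, >= 1.
#' @return Profile values.
#' @export
pearson7 <- function(x, height, center, width, m) {
  height * (1 + ((x - center) / width)^2 * (2^(1 / m) - 1))^(-m)
}

#' Integrated area of a Pearson VII peak
#'
#' Closed form: `height * width * sqrt(pi / (2^(1/m) - 1)) *
#' gamma(m - 1/2) / gamma(m)`.
#'
#' @inheritParams pearson7
#' @return Integrated area.
#' @export
pearson7_area <- function(height, width, m) {
  height * width * sqrt(pi / (2^(1 / m) - 1)) * gamma(m - 0.5) / gamma(m)
}

# height giving a requested integrated area
.pearson7_height <- function(area, width, m) {
  area / pearson7_area(1, width, m)
}

#' Candidate peak windows from local maxima
#'
#' Detects candidate Bragg peaks as local maxima of a lightly smoothed
#' pattern exceeding the background by `min_height` times the robust scale of
#' the signal, and returns fitting windows of half-width `half_width` around
#' each.
#'
#' @param pattern A [diffraction_pattern()].
#' @param half_width Window half-width (nm^-1).
#' @param min_height Prominence threshold in units of the robust
#'   point-to-point noise scale (MAD of first differences).
#' @return Data frame `q_lo`, `q_hi`, `q_peak`.
#' @export
find_peak_windows <- function(pattern, half_width = 0.09, min_height = 8) {
  stopifnot(inherits(pattern, "diffraction_pattern"))
  y <- stats::filter(pattern$intensity, rep(1 / 5, 5), sides = 2)
  y[is.na(y)] <- pattern$intensity[is.na(y)]
  y <- as.numeric(y)
  base <- stats::median(y)
  scale <- max(stats::mad(diff(pattern$intensity)) / sqrt(2),
               1e-4 * (max(y) - base), 1e-12)
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  cand <- which(is_max & y > base + min_height * scale)
  if (length(cand) == 0) {
    return(data.frame(q_lo = numeric(0), q_hi = numeric(0),
                      q_peak = numeric(0)))
  }
  # merge maxima closer than half_width (keep the taller)
  ord <- cand[order(-y[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(pattern$q[i] - pattern$q[kept]) > half_width)) {
      kept <- c(kept, i)
    }
  }
  kept <- sort(kept)
  data.frame(q_lo = pmax(pattern$q[kept] - half_width, min(pattern$q)),
             q_hi = pmin(pattern$q[kept] + half_width, max(pattern$q)),
             q_peak = pattern$q[kept])
}

#' Fit Bragg peaks with a Pearson VII profile
#'
#' Fits, independently in each candidate window, a Pearson VII peak plus a
#' linear local background by Levenberg-Marquardt least squares. The
#' integrated Bragg intensity I_n is the closed-form area of the fitted
#' profile. Non-convergent fits are flagged, never silently dropped.
#'
#' @param pattern A [diffraction_pattern()].
#' @param windows Data frame with columns `q_lo`, `q_hi` (and optionally
#'   `q_peak`); defaults to [find_peak_windows()] output. Each window must
#'   contain at least 8 points.
#' @return Object of class `bragg_peak_fits`: a data frame with one row per
#'   window (`center_q`, `center_se`, `height`, `width`, `shape_m`, `area`,
#'   `fit_rmse`, `converged`, `significant`).
#' @export
fit_bragg_peaks <- function(pattern, windows = find_peak_windows(pattern)) {
  stopifnot(inherits(pattern, "diffraction_pattern"),
            all(c("q_lo", "q_hi") %in% names(windows)))
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    sel <- pattern$q >= windows$q_lo[i] & pattern$q <= windows$q_hi[i]
    if (sum(sel) < 8) stop("window ", i, " contains fewer than 8 data points")
    out[[i]] <- .fit_one_peak(pattern$q[sel], pattern$intensity[sel],
                              if ("q_peak" %in% names(windows))
                                windows$q_peak[i] else NA_real_)
  }
  res <- do.call(rbind, out)
  structure(res, class = c("bragg_peak_fits", "data.frame"))
}

.fit_one_peak <- function(q, y, q_guess = NA_real_) {
  if (is.na(q_guess)) q_guess <- q[which.max(y)]
  b0 <- stats::median(y[c(1:3, (length(y) - 2):length(y))])
  h0 <- max(y) - b0
  span <- diff(range(q))
  fail <- data.frame(center_q = q_guess, center_se = NA_real_,
                     height = NA_real_, width = NA_real_, shape_m = NA_real_,
                     area = 0, bg_intercept = b0, bg_slope = 0,
                     fit_rmse = NA_real_, converged = FALSE,
                     significant = FALSE)
  if (h0 <= 0) return(fail)
  df <- data.frame(q = q, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ pearson7(q, h, c0, w, m) + a + b * (q - c0),
      data = df,
      start = list(h = h0, c0 = q_guess, w = span / 8, m = 1.5,
                   a = b0, b = 0),
      lower = c(0, min(q), span / 200, 1, -Inf, -Inf),
      upper = c(Inf, max(q), span, 30, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail)
  p <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e)
    rep(NA_real_, length(p)))
  rmse <- sqrt(mean(stats::resid(fit)^2))
  sig <- is.finite(se[["h"]]) && p[["h"]] > 3 * se[["h"]] &&
    p[["h"]] > 3 * rmse
  data.frame(center_q = p[["c0"]], center_se = se[["c0"]],
             height = p[["h"]], width = p[["w"]], shape_m = p[["m"]],
             area = pearson7_area(p[["h"]], p[["w"]], p[["m"]]),
             bg_intercept = p[["a"]], bg_slope = p[["b"]],
             fit_rmse = rmse, converged = TRUE, significant = sig)
}

#' Assign diffraction orders and fit the lamellar repeat distance
#'
#' Finds the maximal subset of fitted peaks consistent with the lamellar law
#' q_n = 2 pi n / d. Candidate repeat distances are generated by assuming
#' each peak in turn is order 1..`n_max`; for each candidate, peaks within
#' tolerance of their nearest predicted order are assigned and d is refit by
#' least squares (d = 2 pi sum(n^2) / sum(n q)). The candidate assigning most
#' peaks (ties: smallest residual) wins. Peaks failing equidistance — e.g.
#' the crystalline CHOL reflection at 1.8 nm^-1 or the minor impurity phase
#' at 1.2 nm^-1 — are excluded with a reason.
#'
#' @param peaks A [fit_bragg_peaks()] result (or data frame with `center_q`,
#'   optionally `center_se`, `converged`, `significant`).
#' @param n_max Highest diffraction order considered (default 6; higher
#'   orders are used when present and significant).
#' @param tol_floor Absolute floor of the membership tolerance (nm^-1); the
#'   tolerance is `max(tol_floor, 3 * center_se)` per peak.
#' @return Object of class `lamellar_phase`: list with `d_nm`, `orders`
#'   (data frame `n`, `q`, `center_se`, row index into `peaks`),
#'   `excluded` (data frame `q`, `reason`), `residual_nm` (max |q - 2 pi n/d|).
#' @export
assign_orders <- function(peaks, n_max = 6, tol_floor = 0.02) {
  stopifnot("center_q" %in% names(peaks))
  usable <- rep(TRUE, nrow(peaks))
  if ("converged" %in% names(peaks)) usable <- usable & peaks$converged
  qs <- peaks$center_q[usable]
  ses <- if ("center_se" %in% names(peaks)) peaks$center_se[usable] else
    rep(NA_real_, length(qs))
  idx <- which(usable)
  if (length(qs) < 2) stop("need at least 2 fitted peaks to assign orders")
  tol <- pmax(tol_floor, ifelse(is.finite(ses), 3 * ses, 0))

  best <- NULL
  for (i in seq_along(qs)) {
    for (n1 in seq_len(n_max)) {
      d_cand <- 2 * pi * n1 / qs[i]
      for (pass in 1:2) {
        n_assigned <- round(qs * d_cand / (2 * pi))
        ok <- n_assigned >= 1 & n_assigned <= max(n_max, n_assigned[i]) &
          abs(qs - 2 * pi * n_assigned / d_cand) <= tol
        # one peak per order: keep the closest
        if (any(ok)) {
          for (n0 in unique(n_assigned[ok])) {
            dup <- which(ok & n_assigned == n0)
            if (length(dup) > 1) {
              keep <- dup[which.min(abs(qs[dup] - 2 * pi * n0 / d_cand))]
              ok[setdiff(dup, keep)] <- FALSE
            }
          }
        }
        if (sum(ok) < 2) break
        d_cand <- 2 * pi * sum(n_assigned[ok]^2) / sum(n_assigned[ok] * qs[ok])
      }
      if (sum(ok) < 2) next
      resid <- max(abs(qs[ok] - 2 * pi * n_assigned[ok] / d_cand))
      cand <- list(d = d_cand, ok = ok, n = n_assigned, resid = resid)
      if (is.null(best) || sum(ok) > sum(best$ok) ||
          (sum(ok) == sum(best$ok) && resid < best$resid)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    stop("no equidistant subset of >= 2 peaks found; cannot index the ",
         "lamellar phase")
  }
  ok <- best$ok
  orders <- data.frame(n = best$n[ok], q = qs[ok], center_se = ses[ok],
                       peak_row = idx[ok])
  orders <- orders[order(orders$n), ]
  excl_q <- qs[!ok]
  excluded <- data.frame(
    q = excl_q,
    reason = rep("not equidistant with the lamellar series", length(excl_q))
  )
  if (any(!usable)) {
    excluded <- rbind(excluded, data.frame(
      q = peaks$center_q[!usable],
      reason = rep("fit did not converge", sum(!usable))))
  }
  structure(list(d_nm = best$d, orders = orders, excluded = excluded,
                 residual_nm = best$resid, n_max = n_max),
            class = "lamellar_phase")
}

#' @export
print.lamellar_phase <- function(x, ...) {
  cat("Lamellar phase: d =", format(x$d_nm, digits = 5), "nm;",
      nrow(x$orders), "orders assigned;", nrow(x$excluded),
      "peak(s) excluded\n")
  invisible(x)
}

#' Absorption correction for an oriented lipid film
#'
#' `A_n = [ sin(theta)/(2 mu l) * (1 - exp(-2 mu l / sin(theta))) ]^-1`,
#' the slab absorption factor for a film of thickness l and linear
#' attenuation coefficient mu in symmetric reflection. A_n >= 1, tending to 1
#' in the optically thin limit.
#'
#' @param theta_rad Bragg angle (radians), 0 < theta < pi/2.
#' @param mu_per_mm Linear attenuation coefficient (mm^-1), >= 0.
#' @param l_mm Film thickness (mm), > 0.
#' @return Correction factor A_n.
#' @export
#' @examples
#' absorption_correction(0.1, 0, 0.03)       # 1 (no absorption)
absorption_correction <- function(theta_rad, mu_per_mm, l_mm) {
  if (any(mu_per_mm < 0)) stop("mu must be >= 0")
  if (any(l_mm <= 0)) stop("film thickness must be positive")
  if (any(theta_rad <= 0 | theta_rad >= pi / 2)) {
    stop("theta must lie strictly between 0 and pi/2 (grazing limit undefined)")
  }
  x <- 2 * mu_per_mm * l_mm / sin(theta_rad)
  ifelse(x == 0, 1, x / (-expm1(-x)))
}

#' Structure-factor amplitudes from indexed peak intensities
#'
#' |F_n| = sqrt(A_n * L * I_n) with the Lorentz correction L = q_n (the
#' oriented-multilayer rule) and A_n the slab absorption correction. With
#' `mu_per_mm = 0` (or unknown geometry) A_n = 1.
#'
#' @param phase A [assign_orders()] result.
#' @param peaks The [fit_bragg_peaks()] result the phase was built from.
#' @param mu_per_mm Linear attenuation coefficient (mm^-1); 0 disables the
#'   absorption correction.
#' @param thickness_mm Film thickness (mm).
#' @param wavelength_nm Wavelength used to convert q_n to theta for A_n
#'   (required when `mu_per_mm > 0`).
#' @param d2o_fraction Buffer D2O percentage carried as metadata.
#' @return A [structure_factor_set()] with unsigned amplitudes (`F` =
#'   `amplitude`, sign undetermined) and per-order corrections in columns
#'   `I_n`, `lorentz_L`, `absorption_A`.
#' @export
structure_factor_amplitudes <- function(phase, peaks, mu_per_mm = 0,
                                        thickness_mm = 0.03,
                                        wavelength_nm = NULL,
                                        d2o_fraction = NA_real_) {
  stopifnot(inherits(phase, "lamellar_phase"))
  ord <- phase$orders
  I_n <- peaks$area[ord$peak_row]
  q_n <- 2 * pi * ord$n / phase$d_nm
  if (mu_per_mm > 0) {
    if (is.null(wavelength_nm)) {
      stop("wavelength_nm is required when mu_per_mm > 0")
    }
    theta <- asin(q_n * wavelength_nm / (4 * pi))
    A_n <- absorption_correction(theta, mu_per_mm, thickness_mm)
  } else {
    A_n <- rep(1, length(q_n))
  }
  amp <- sqrt(pmax(A_n * q_n * I_n, 0))
  structure_factor_set(ord$n, amp, d_nm = phase$d_nm,
                       d2o_fraction = d2o_fraction,
                       extra = data.frame(I_n = I_n, lorentz_L = q_n,
                                          absorption_A = A_n))
}

#' One-step reduction of a diffraction pattern
#'
#' Convenience wrapper: detect windows, fit Pearson VII peaks, assign orders,
#' and compute corrected structure-factor amplitudes.
#'
#' @inheritParams structure_factor_amplitudes
#' @param pattern A [diffraction_pattern()].
#' @param n_max Highest order considered.
#' @param windows Optional fitting windows (see [fit_bragg_peaks()]).
#' @return List with `peaks`, `phase`, `sfs`.
#' @export
reduce_pattern <- function(pattern, n_max = 6, windows = NULL,
                           mu_per_mm = 0, thickness_mm = 0.03,
                           wavelength_nm = NULL) {
  if (is.null(windows)) windows <- find_peak_windows(pattern)
  peaks <- fit_bragg_peaks(pattern, windows)
  phase <- assign_orders(peaks, n_max = n_max)
  sfs <- structure_factor_amplitudes(
    phase, peaks, mu_per_mm = mu_per_mm, thickness_mm = thickness_mm,
    wavelength_nm = wavelength_nm,
    d2o_fraction = attr(pattern, "d2o_fraction"))
  list(peaks = peaks, phase = phase, sfs = sfs)
}
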