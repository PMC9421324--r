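#' Fourier synthesis of the unit-cell SLD profile
#'
#' rho(x) = F0 + 2 sum_{n=1}^{n_max} F_n cos(2 pi n x / d) on a symmetric
#' grid over \[-d/2, d/2\]. The cosine-only synthesis encodes the
#' centrosymmetry of the unit cell; it requires every included order to carry
#' a determined sign.
#'
#' @param sfs A signed [structure_factor_set()] (see [apply_phase_signs()]).
#' @param F0 Mean SLD level (e.g. from [compute_F0()]); default 0 puts the
#'   profile on a relative scale.
#' @param d Repeat distance (nm); defaults to the set's own.
#' @param grid_n Number of grid points (default 1201, ~0.01 nm spacing at
#'   d = 12.6 nm — below the position-reporting precision).
#' @return Object of class `sld_profile`: data frame `x`, `rho` with
#'   attributes `d_nm`, `F0`, `orders`, `F` and `provenance`.
#' @export
fourier_synthesis <- function(sfs, F0 = 0, d = attr(sfs, "d_nm"),
                              grid_n = 1201) {
  stopifnot(inherits(sfs, "structure_factor_set"), d > 0, grid_n >= 3)
  if (any(is.na(sfs$F))) {
    stop("ambiguous phase signs for order(s) ",
         paste(sfs$n[is.na(sfs$F)], collapse = ", "),
         "; resolve or drop them before synthesis")
  }
  x <- seq(-d / 2, d / 2, length.out = grid_n)
  rho <- rep(F0, grid_n)
  for (i in seq_len(nrow(sfs))) {
    rho <- rho + 2 * sfs$F[i] * cos(2 * pi * sfs$n[i] * x / d)
  }
  sld_profile(x, rho, d_nm = d, F0 = F0, orders = sfs$n, F = sfs$F,
              provenance = list(d2o_fraction = attr(sfs, "d2o_fraction")))
}

#' Construct an SLD profile object
#'
#' @param x Symmetric grid over \[-d/2, d/2\] (nm).
#' @param rho SLD values.
#' @param d_nm Repeat distance.
#' @param F0 Mean level.
#' @param orders,F Orders and signed coefficients used (for provenance).
#' @param provenance Free-form provenance list.
#' @return Object of class `sld_profile`.
#' @export
sld_profile <- function(x, rho, d_nm, F0 = NA_real_, orders = NULL, F = NULL,
                        provenance = list()) {
  stopifnot(length(x) == length(rho))
  structure(data.frame(x = x, rho = rho),
            class = c("sld_profile", "data.frame"),
            d_nm = d_nm, F0 = F0, orders = orders, F = F,
            provenance = provenance)
}

#' Difference of two SLD profiles
#'
#' Pointwise a - b after mapping both onto a common grid in fractional
#' coordinates x/d (so a repeat-distance mismatch of up to `d_tol` is
#' absorbed). Used for the water profile (100% minus 8% hydration of the
#' same sample) and for deuterated-label profiles (deuterated minus protiated
#' sample, both at the 8% null contrast).
#'
#' @param profile_a,profile_b [sld_profile()]s.
#' @param d_tol Maximum relative repeat-distance mismatch (default 0.01).
#' @return An `sld_profile` on profile_a's grid; its provenance records the
#'   operands.
#' @export
difference_profile <- function(profile_a, profile_b, d_tol = 0.01) {
  stopifnot(inherits(profile_a, "sld_profile"),
            inherits(profile_b, "sld_profile"))
  da <- attr(profile_a, "d_nm"); db <- attr(profile_b, "d_nm")
  if (abs(da - db) / da > d_tol) {
    stop("repeat distances differ by more than ", 100 * d_tol, "% (",
         format(da), " vs ", format(db), " nm)")
  }
  # common grid: fractional coordinate of profile_a
  fb <- profile_b$x / db
  rb <- stats::approx(fb, profile_b$rho, xout = profile_a$x / da,
                      rule = 2)$y
  sld_profile(profile_a$x, profile_a$rho - rb, d_nm = da,
              F0 = attr(profile_a, "F0") - attr(profile_b, "F0"),
              provenance = list(
                a = attr(profile_a, "provenance"),
                b = attr(profile_b, "provenance"),
                operation = "difference"))
}

#' Locate profile maxima with sub-grid refinement
#'
#' Local maxima by neighbour comparison with three-point parabolic
#' refinement; the periodic boundary at x = +/- d/2 is treated as a regular
#' grid point via the wrapped neighbour. Symmetric pairs (x and -x within
#' `pair_tol`) are reported once with `pair = TRUE` (read as +/- position).
#' Secondary maxima are reported with their height relative to the tallest.
#'
#' @param profile An [sld_profile()].
#' @param region Optional c(lo, hi) restricting the search (applied to |x|).
#' @param min_rel_height Discard maxima below this fraction of the tallest
#'   (after subtracting the profile minimum).
#' @param pair_tol Pairing tolerance (nm).
#' @return Data frame `position_nm`, `value`, `relative_height`, `pair`,
#'   `uncertainty_nm` (curvature-based half-width of the parabolic fit at the
#'   grid noise level), sorted by decreasing value. Zero rows for a flat
#'   profile.
#' @export
locate_extrema <- function(profile, region = NULL, min_rel_height = 0.1,
                           pair_tol = 0.2) {
  stopifnot(inherits(profile, "sld_profile"))
  x <- profile$x
  y <- profile$rho
  n <- length(x)
  d <- attr(profile, "d_nm")
  if (max(y) - min(y) < 1e-12 * max(abs(y), 1)) {
    return(data.frame(position_nm = numeric(0), value = numeric(0),
                      relative_height = numeric(0), pair = logical(0),
                      uncertainty_nm = numeric(0)))
  }
  # periodic wrap: x[1] and x[n] are the same physical point
  yl <- c(y[n - 1], y[1:(n - 1)])
  yr <- c(y[2:n], y[2])
  ymid <- y
  is_max <- ymid > yl & ymid >= yr
  is_max[n] <- FALSE  # identical to point 1 under periodicity
  idx <- which(is_max)
  if (length(idx) == 0) {
    return(data.frame(position_nm = numeric(0), value = numeric(0),
                      relative_height = numeric(0), pair = logical(0),
                      uncertainty_nm = numeric(0)))
  }
  h <- x[2] - x[1]
  ref <- t(vapply(idx, function(i) {
    y0 <- y[i]; ym <- yl[i]; yp <- yr[i]
    denom <- ym - 2 * y0 + yp
    delta <- if (denom < 0) 0.5 * (ym - yp) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    pos <- x[i] + delta * h
    val <- y0 - 0.25 * (ym - yp) * delta
    curv <- denom / h^2
    unc <- if (curv < 0) sqrt(abs(2 * h^2 / denom)) * h else NA_real_
    c(pos, val, unc)
  }, numeric(3)))
  out <- data.frame(position_nm = ref[, 1], value = ref[, 2],
                    uncertainty_nm = ref[, 3])
  # wrap positions beyond the boundary back into [-d/2, d/2]
  out$position_nm <- ((out$position_nm + d / 2) %% d) - d / 2
  if (!is.null(region)) {
    out <- out[abs(out$position_nm) >= region[1] &
                 abs(out$position_nm) <= region[2], , drop = FALSE]
  }
  if (nrow(out) == 0) {
    out$relative_height <- numeric(0)
    out$pair <- logical(0)
    return(out[, c("position_nm", "value", "relative_height", "pair",
                   "uncertainty_nm")])
  }
  base <- min(y)
  out$relative_height <- (out$value - base) / (max(out$value) - base)
  out <- out[out$relative_height >= min_rel_height, , drop = FALSE]
  # merge symmetric pairs
  out <- out[order(-out$value), , drop = FALSE]
  out$pair <- FALSE
  drop <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (drop[i]) next
    j <- which(!drop & seq_len(nrow(out)) > i &
                 abs(out$position_nm + out$position_nm[i]) < pair_tol &
                 abs(abs(out$position_nm) - abs(out$position_nm[i])) < pair_tol)
    if (length(j) > 0) {
      out$pair[i] <- TRUE
      out$position_nm[i] <- abs(out$position_nm[i])
      drop[j[1]] <- TRUE
    }
  }
  out <- out[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out[, c("position_nm", "value", "relative_height", "pair",
          "uncertainty_nm")]
}

#' Relative-absolute scaling of a label difference profile
#'
#' Fits a Gaussian to the dominant peak of a deuterated-label difference
#' profile to obtain the peak height (SLD_h) and fitted peak area (SLD_a).
#' Given the expected label scattering SLD_dif — the deuteration excess the
#' label must account for, computed from composition via
#' [expected_label_scattering()] — the corrected height is
#' SLD_correct = SLD_h x SLD_dif / SLD_a and the multiplicative scale factor
#' SLD_correct / SLD_h = SLD_dif / SLD_a. For an off-centre (mirrored) label
#' the fitted single-peak area is doubled before scaling so that SLD_a is
#' the whole-cell label area.
#'
#' @param label_profile An [sld_profile()] difference profile with a dominant
#'   label peak.
#' @param expected_label_scattering SLD_dif in profile-area units
#'   (SLD x nm per unit cell).
#' @param center Optional initial guess for the peak centre (nm); default:
#'   position of the profile maximum.
#' @return Object of class `scaling_fit`: list with `sld_h`, `sld_a`,
#'   `sld_dif`, `sld_correct`, `scale_factor`, `center_nm`, `sigma_nm` and
#'   the `scaled_profile`.
#' @export
relative_absolute_scale <- function(label_profile, expected_label_scattering,
                                    center = NULL) {
  stopifnot(inherits(label_profile, "sld_profile"),
            expected_label_scattering > 0)
  x <- label_profile$x
  y <- label_profile$rho
  if (is.null(center)) center <- x[which.max(y)]
  d <- attr(label_profile, "d_nm")
  sel <- abs(x - center) <= d / 6
  df <- data.frame(x = x[sel], y = y[sel])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ h * exp(-(x - c0)^2 / (2 * s^2)) + b,
      data = df,
      start = list(h = max(df$y) - min(df$y), c0 = center,
                   s = 0.5, b = min(df$y)),
      lower = c(0, min(df$x), 0.05, -Inf),
      upper = c(Inf, max(df$x), d / 4, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) stop("Gaussian fit of the label peak failed")
  p <- stats::coef(fit)
  sld_h <- p[["h"]]
  area_single <- p[["h"]] * p[["s"]] * sqrt(2 * pi)
  if (area_single <= 0) stop("fitted label peak area is not positive")
  mirrored <- abs(p[["c0"]]) > 3 * p[["s"]] / 2  # off-centre => mirrored pair
  sld_a <- if (mirrored) 2 * area_single else area_single
  scale_factor <- expected_label_scattering / sld_a
  scaled <- label_profile
  scaled$rho <- scaled$rho * scale_factor
  structure(list(
    sld_h = sld_h, sld_a = sld_a, sld_dif = expected_label_scattering,
    sld_correct = sld_h * scale_factor, scale_factor = scale_factor,
    center_nm = p[["c0"]], sigma_nm = p[["s"]], mirrored = mirrored,
    scaled_profile = scaled
  ), class = "scaling_fit")
}

#' Expected label scattering from the deuteration pattern
#'
#' The integrated excess scattering the deuterated chains contribute to one
#' unit cell, per unit membrane area: deuteron count per molecule x molar
#' ratio x (b_D - b_H) / area per lipid. Expressed in the same units as the
#' area under an SLD(x) difference profile (1e-6 A^-2 x nm) so it can be fed
#' directly to [relative_absolute_scale()].
#'
#' @param n_deuterons Deuterons per labelled molecule (e.g. 7 for the
#'   terminally deuterated sphingosine chain, 47 for a perdeuterated C24
#'   acyl chain).
#' @param molar_fraction Labelled molecules per lipid in the unit cell
#'   (molar ratio of the labelled species over the total).
#' @param area_per_lipid_A2 Mean in-plane area per lipid molecule (A^2).
#' @param molecules_per_cell Lipid molecules stacked per unit cell along the
#'   normal (3 for the trilayer).
#' @return SLD_dif in 1e-6 A^-2 x nm.
#' @export
expected_label_scattering <- function(n_deuterons, molar_fraction,
                                      area_per_lipid_A2 = 40,
                                      molecules_per_cell = 3) {
  stopifnot(n_deuterons > 0, molar_fraction > 0, area_per_lipid_A2 > 0)
  b <- neutron_scattering_lengths()
  db_fm <- n_deuterons * (b[["D"]] - b[["H"]])
  # fm -> 1e-5 A; per area A^2 -> A^-1; report 1e-6 A^-2 * nm (1 nm = 10 A)
  db_fm * 1e-5 / area_per_lipid_A2 * molar_fraction * molecules_per_cell *
    1e6 / 10
}
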