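#' Build a contrast series from per-fraction structure-factor sets
#'
#' Collects the per-order amplitudes measured at several D2O/H2O buffer
#' fractions into a long table, the input of the phasing step.
#'
#' @param sfs_list List of [structure_factor_set()]s, one per fraction (the
#'   fraction is read from each set's `d2o_fraction` attribute, or from the
#'   list names).
#' @param sample_id Sample identifier.
#' @return Object of class `contrast_series`: list with `data` (data frame
#'   `order`, `fraction`, `amplitude`), `d_nm`, `sample_id`,
#'   `regressions` (filled by [fit_contrast_regression()]).
#' @export
build_contrast_series <- function(sfs_list, sample_id = NA_character_) {
  stopifnot(is.list(sfs_list), length(sfs_list) >= 2)
  rows <- list()
  ds <- numeric(0)
  for (i in seq_along(sfs_list)) {
    s <- sfs_list[[i]]
    stopifnot(inherits(s, "structure_factor_set"))
    fr <- attr(s, "d2o_fraction")
    if (is.na(fr) && !is.null(names(sfs_list))) {
      fr <- as.numeric(names(sfs_list)[i])
    }
    if (is.na(fr)) stop("D2O fraction unknown for series element ", i)
    rows[[i]] <- data.frame(order = s$n, fraction = fr,
                            amplitude = s$amplitude)
    ds <- c(ds, attr(s, "d_nm"))
  }
  dat <- do.call(rbind, rows)
  if (length(unique(dat$fraction)) < 2) {
    stop("contrast series needs at least two distinct D2O fractions")
  }
  structure(list(data = dat, d_nm = mean(ds), sample_id = sample_id,
                 regressions = NULL),
            class = "contrast_series")
}

# OLS of y on x returning slope/intercept/R2/SEs without lm overhead
.ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  sst <- sum((y - my)^2)
  dfree <- n - 2
  sigma2 <- if (dfree > 0) sse / dfree else 0
  list(slope = slope, intercept = intercept, sse = sse,
       r_squared = if (sst > 0) 1 - sse / sst else 1,
       slope_se = sqrt(sigma2 / sxx),
       sigma = sqrt(sigma2))
}

# Best piecewise-sign assignment: signed amplitudes must lie on one line
# whose high-fraction end carries sign `end_sign`; a single zero crossing is
# allowed, so candidate sign sequences flip a prefix of the sorted fractions.
.best_signed_line <- function(fractions, amplitudes, end_sign = 1) {
  ord <- order(fractions)
  x <- fractions[ord]
  a <- amplitudes[ord]
  m <- length(x)
  best <- NULL
  for (k in 0:m) {
    s <- c(rep(-end_sign, k), rep(end_sign, m - k))
    fit <- .ols_line(x, s * a)
    if (is.null(best) || fit$sse < best$fit$sse - 1e-15) {
      best <- list(fit = fit, signs = s, k = k)
    }
  }
  best$fractions <- x
  best$signed <- best$signs * a
  best
}

#' Per-order linear regression of structure factors on D2O fraction
#'
#' Ordinary least squares of (signed-candidate) amplitude versus buffer
#' fraction for every diffraction order. Linearity of the signed structure
#' factors in the buffer composition is the experimental signature of a
#' centrosymmetric unit cell, so the per-order R^2 doubles as a
#' centrosymmetry check.
#'
#' @param series A [build_contrast_series()] result.
#' @param signs Optional trial sign vector (one per order, e.g. a water-based
#'   assignment) applied to the amplitudes before regression; without it each
#'   order is regressed through its best single-crossing sign pattern.
#' @return The series with `regressions` filled: data frame `order`, `slope`,
#'   `intercept`, `r_squared`, `slope_se`.
#' @export
fit_contrast_regression <- function(series, signs = NULL) {
  stopifnot(inherits(series, "contrast_series"))
  dat <- series$data
  orders <- sort(unique(dat$order))
  out <- data.frame(order = orders, slope = NA_real_, intercept = NA_real_,
                    r_squared = NA_real_, slope_se = NA_real_)
  for (i in seq_along(orders)) {
    sel <- dat$order == orders[i]
    if (sum(sel) < 2) stop("order ", orders[i], " has fewer than 2 fractions")
    end_sign <- if (is.null(signs)) 1 else signs[i]
    if (is.na(end_sign)) end_sign <- 1
    b <- .best_signed_line(dat$fraction[sel], dat$amplitude[sel], end_sign)
    out$slope[i] <- b$fit$slope
    out$intercept[i] <- b$fit$intercept
    out$r_squared[i] <- b$fit$r_squared
    out$slope_se[i] <- b$fit$slope_se
  }
  series$regressions <- out
  series
}

#' Exhaustive sign search scored by water-profile plausibility
#'
#' Scores every sign combination of the supplied per-order magnitudes by how
#' plausible the implied water profile is. Two physical facts anchor the
#' score: in a lamellar phase the lipid head groups — and with them the
#' water — sit at the unit-cell boundary (with further bands allowed inside),
#' and a water density cannot be substantially negative. Each combination is
#' scored by the boundary value of the cosine synthesis (in units of the
#' profile RMS) minus twice the negative-energy fraction; combinations
#' implying implausible water profiles thereby score low and are discarded.
#'
#' @param magnitudes Per-order coefficient magnitudes (order 1..n).
#' @param d_nm Repeat distance.
#' @param n_grid Grid points for the scoring synthesis.
#' @return List with `signs` (best combination), `score`, and the full
#'   `scores` vector (one per combination, in binary order).
#' @export
best_sign_combination <- function(magnitudes, d_nm, n_grid = 241) {
  n <- length(magnitudes)
  stopifnot(n >= 1, n <= 12, d_nm > 0)
  x <- seq(-d_nm / 2, d_nm / 2, length.out = n_grid)
  basis <- sapply(seq_len(n), function(k) cos(2 * pi * k * x / d_nm))
  combos <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  scores <- apply(combos, 1, function(s) {
    rho <- 2 * basis %*% (s * magnitudes)
    rms <- sqrt(mean(rho^2))
    if (rms == 0) return(-Inf)
    boundary <- 2 * sum(s * magnitudes * (-1)^seq_len(n))  # rho at x = d/2
    boundary / rms - 2 * sum(pmin(rho, 0)^2) / sum(rho^2)
  })
  best <- which.max(scores)
  list(signs = as.integer(combos[best, ]), score = scores[best],
       scores = scores)
}

#' Phase signs of the water profile from a contrast series
#'
#' The water-associated Fourier coefficient of each order is estimated from
#' the slope of the structure-factor amplitudes across the D2O/H2O series
#' (difference between the 100% and 8% hydrations). The slope fixes each
#' order's water coefficient magnitude; the per-order signs are then fixed by
#' the physical requirement that the implied water profile be concentrated in
#' positive bands at the head-group planes (sign combinations producing
#' implausible water profiles are discarded via [best_sign_combination()]).
#' Orders whose slope is indistinguishable from zero (|slope| < 2 SE, or an
#' exactly flat series) are flagged ambiguous and excluded.
#'
#' @param series A [build_contrast_series()] result; the fractions must
#'   include the 8% and 100% extremes.
#' @param require_extremes Check that 8 and 100 are present (default TRUE).
#' @return Object of class `phase_assignment`: list with `signs` (+1/-1/NA
#'   per order), `basis = "water"`, `diagnostics` data frame.
#' @export
assign_water_phases <- function(series, require_extremes = TRUE) {
  stopifnot(inherits(series, "contrast_series"))
  fr <- unique(series$data$fraction)
  if (require_extremes && !(any(abs(fr - 8) < 1e-6) &&
                            any(abs(fr - 100) < 1e-6))) {
    stop("contrast series must include the 8% and 100% D2O extremes")
  }
  dat <- series$data
  orders <- sort(unique(dat$order))
  mag <- numeric(length(orders))
  se <- numeric(length(orders))
  r2 <- numeric(length(orders))
  for (i in seq_along(orders)) {
    sel <- dat$order == orders[i]
    b <- .best_signed_line(dat$fraction[sel], dat$amplitude[sel], 1)
    mag[i] <- abs(b$fit$slope)
    se[i] <- b$fit$slope_se
    r2[i] <- b$fit$r_squared
  }
  floor_mag <- 1e-9 * max(dat$amplitude, 1e-300)
  ambiguous <- mag <= pmax(2 * se, floor_mag)
  reason <- ifelse(ambiguous, "water slope indistinguishable from zero", "")
  signs <- rep(NA_integer_, length(orders))
  if (any(!ambiguous)) {
    search <- best_sign_combination(ifelse(ambiguous, 0, mag), series$d_nm)
    signs[!ambiguous] <- search$signs[!ambiguous]
  }
  structure(list(
    signs = signs, basis = "water",
    diagnostics = data.frame(order = orders, slope_magnitude = mag,
                             slope_se = se, r_squared = r2,
                             ambiguous = ambiguous, reason = reason)
  ), class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  lab <- ifelse(is.na(x$signs), "?", ifelse(x$signs > 0, "+", "-"))
  cat("Phase assignment (", x$basis, " basis): ",
      paste(lab, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Phase signs of a sample from its contrast series and the water signs
#'
#' Starts from the water sign of each order and applies the x-axis crossing
#' rule: the signed structure factors of a centrosymmetric sample lie on a
#' line in buffer fraction whose slope carries the water sign; if that line
#' crosses zero between the 8% and 100% fractions, the sign at 8% — which is
#' the sample's lipid-only sign — is opposite to the water sign, and the
#' order's sign is flipped. Ambiguous water orders propagate as ambiguous.
#'
#' @param series A [build_contrast_series()] result for the sample; must
#'   contain the 8% fraction.
#' @param water_assignment A [assign_water_phases()] result (or any
#'   `phase_assignment`).
#' @return Object of class `phase_assignment` with `basis = "sample"`;
#'   diagnostics record the fitted line, crossing fraction and flip flag per
#'   order.
#' @export
assign_sample_phases <- function(series, water_assignment) {
  stopifnot(inherits(series, "contrast_series"),
            inherits(water_assignment, "phase_assignment"))
  dat <- series$data
  if (!any(abs(dat$fraction - 8) < 1e-6)) {
    stop("sample phasing requires the 8% D2O fraction")
  }
  orders <- sort(unique(dat$order))
  w <- water_assignment$signs
  if (length(w) < length(orders)) {
    stop("water assignment covers fewer orders than the series")
  }
  signs <- rep(NA_integer_, length(orders))
  flipped <- rep(NA, length(orders))
  crossing <- rep(NA_real_, length(orders))
  slope <- rep(NA_real_, length(orders))
  at8 <- rep(NA_real_, length(orders))
  r2 <- rep(NA_real_, length(orders))
  reason <- rep("", length(orders))
  for (i in seq_along(orders)) {
    if (is.na(w[i])) {
      reason[i] <- "ambiguous water sign propagated"
      next
    }
    sel <- dat$order == orders[i]
    b <- .best_signed_line(dat$fraction[sel], dat$amplitude[sel],
                           end_sign = w[i])
    pred8 <- b$fit$intercept + b$fit$slope * 8
    slope[i] <- b$fit$slope
    at8[i] <- pred8
    r2[i] <- b$fit$r_squared
    if (pred8 == 0) {
      reason[i] <- "structure factor vanishes at 8%"
      next
    }
    signs[i] <- as.integer(sign(pred8))
    flipped[i] <- signs[i] != w[i]
    if (abs(b$fit$slope) > 0) {
      x0 <- -b$fit$intercept / b$fit$slope
      if (x0 > 8 && x0 < 100) crossing[i] <- x0
    }
  }
  structure(list(
    signs = signs, basis = "sample",
    diagnostics = data.frame(order = orders, water_sign = w[seq_along(orders)],
                             slope = slope, F_at_8 = at8, r_squared = r2,
                             crossing_fraction = crossing, flipped = flipped,
                             reason = reason)
  ), class = "phase_assignment")
}

#' Apply phase signs to measured amplitudes
#'
#' @param sfs A [structure_factor_set()] with unsigned amplitudes.
#' @param assignment A `phase_assignment` covering the set's orders.
#' @return The set with signed `F` (ambiguous orders get NA and are flagged).
#' @export
apply_phase_signs <- function(sfs, assignment) {
  stopifnot(inherits(sfs, "structure_factor_set"),
            inherits(assignment, "phase_assignment"))
  s <- assignment$signs[sfs$n]
  sfs$F <- sfs$amplitude * s
  sfs
}
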