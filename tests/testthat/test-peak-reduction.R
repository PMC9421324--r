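test_that("angle-to-q conversion follows Bragg geometry", {
  expect_equal(q_from_angle(0, 0.5), 0)
  expect_equal(q_from_angle(10, 0.5), 2 * q_from_angle(10, 1.0))
  # direct high-precision evaluation of 4 pi sin(2.5 deg) / 0.25
  expect_equal(q_from_angle(5, 0.25),
               4 * pi * sin(2.5 * pi / 180) / 0.25, tolerance = 1e-12)
  expect_equal(q_from_angle(5, 0.25), 2.193, tolerance = 1e-3)
  expect_error(q_from_angle(5, 0), "wavelength")
})

test_that("film thickness follows mass/(density x area)", {
  expect_equal(estimate_film_thickness(10, 10, 1.0), 0.01)
  expect_equal(estimate_film_thickness(10, 10, 0.5),
               2 * estimate_film_thickness(10, 10, 1.0))
  expect_equal(estimate_film_thickness(10, 4.56, 0.9),
               10 / (0.9 * 4.56) * 1e-2, tolerance = 1e-12)
  expect_equal(estimate_film_thickness(10, 4.56, 0.9), 0.024,
               tolerance = 0.02)
  expect_error(estimate_film_thickness(10, 0, 1), "positive")
})

test_that("Pearson VII parameters are recovered from a noiseless peak", {
  q <- seq(1.4, 1.6, by = 0.001)
  y <- pearson7(q, height = 5, center = 1.497, width = 0.013, m = 2.2) +
    0.03 + 0.01 * (q - 1.5)
  pat <- diffraction_pattern(q, y)
  fit <- fit_bragg_peaks(pat, data.frame(q_lo = 1.4, q_hi = 1.6))
  expect_true(fit$converged)
  expect_equal(fit$center_q, 1.497, tolerance = 1e-5)
  expect_equal(fit$height, 5, tolerance = 1e-3 * 5)
  expect_equal(fit$width, 0.013, tolerance = 1e-3 * 0.013)
  expect_equal(fit$area, pearson7_area(5, 0.013, 2.2), tolerance = 1e-3)
})

test_that("a flat window yields near-zero area flagged non-significant", {
  q <- seq(1, 1.2, by = 0.002)
  pat <- diffraction_pattern(q, rep(0.05, length(q)))
  fit <- fit_bragg_peaks(pat, data.frame(q_lo = 1, q_hi = 1.2))
  expect_false(fit$significant)
  expect_lt(abs(fit$area), 1e-3)
})

test_that("window fits are independent of processing order", {
  sfs <- profile_to_structure_factors(prot_model(), 100)
  pat <- synthesize_pattern(sfs, config = noiseless_config())
  w <- find_peak_windows(pat)
  f1 <- fit_bragg_peaks(pat, w)
  f2 <- fit_bragg_peaks(pat, w[rev(seq_len(nrow(w))), ])
  expect_equal(f1$area[order(f1$center_q)], f2$area[order(f2$center_q)],
               tolerance = 1e-12)
})

test_that("order assignment recovers d and excludes non-lamellar peaks", {
  peaks <- data.frame(center_q = c(0.5 * 1:6), center_se = rep(1e-4, 6))
  ph <- assign_orders(peaks)
  expect_equal(ph$d_nm, 2 * pi / 0.5, tolerance = 1e-9)
  expect_equal(ph$orders$n, 1:6)

  peaks2 <- rbind(peaks, data.frame(center_q = 1.8, center_se = 1e-4))
  ph2 <- assign_orders(peaks2)
  expect_equal(nrow(ph2$orders), 6)
  expect_true(1.8 %in% ph2$excluded$q)
  expect_equal(ph2$d_nm, ph$d_nm, tolerance = 1e-9)

  expect_error(assign_orders(peaks[1, , drop = FALSE]), "at least 2")
})

test_that("order assignment is scale-consistent and tolerance-respecting", {
  peaks <- data.frame(center_q = 0.4987 * 1:6 + c(1, -1, 2, 0, -2, 1) * 1e-3,
                      center_se = rep(2e-3, 6))
  ph <- assign_orders(peaks)
  for (cc in c(0.5, 2)) {
    ph_c <- assign_orders(transform(peaks, center_q = center_q * cc))
    expect_equal(ph_c$d_nm, ph$d_nm / cc, tolerance = 1e-9)
  }
  expect_lte(ph$residual_nm, max(0.02, 3 * 2e-3))
})

test_that("d is recovered within 0.05 nm under 0.2% centre jitter", {
  d_true <- 12.57
  q_true <- 2 * pi * (1:6) / d_true
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    qj <- q_true * (1 + 0.002 * rnorm(6))
    ph <- assign_orders(data.frame(center_q = qj, center_se = 0.002 * q_true))
    worst <- max(worst, abs(ph$d_nm - d_true))
  }
  expect_lt(worst, 0.05)
})

test_that("absorption correction has the right limits and monotonicity", {
  expect_equal(absorption_correction(0.2, 1e-9, 0.03), 1, tolerance = 1e-6)
  # x = 2 mu l / sin(theta) = 1
  th <- 0.3
  mu <- sin(th) / (2 * 0.03)
  expect_equal(absorption_correction(th, mu, 0.03), 1 / (1 - exp(-1)),
               tolerance = 1e-12)
  mus <- seq(0.1, 20, length.out = 30)
  As <- absorption_correction(0.2, mus, 0.03)
  expect_true(all(diff(As) > 0))
  expect_true(all(As >= 1))
  expect_error(absorption_correction(0, 1, 0.03), "theta")
})

test_that("structure-factor amplitudes scale as sqrt of intensity", {
  peaks <- data.frame(center_q = 0.5 * 1:3, center_se = rep(1e-4, 3),
                      area = c(0, 1, 4), converged = TRUE)
  ph <- assign_orders(peaks)
  sfs <- structure_factor_amplitudes(ph, peaks)
  expect_equal(sfs$amplitude[1], 0)
  peaks4 <- transform(peaks, area = area * 4)
  sfs4 <- structure_factor_amplitudes(ph, peaks4)
  expect_equal(sfs4$amplitude, 2 * sfs$amplitude, tolerance = 1e-12)
})

test_that("synthesize -> reduce round trip recovers |F_n| to 0.1% (noise 0)", {
  cfg <- noiseless_config(extra_peaks = no_extras())
  for (fr in c(8, 100)) {
    sfs <- profile_to_structure_factors(prot_model(), fr)
    red <- reduce_pattern(synthesize_pattern(sfs, config = cfg))
    expect_equal(red$phase$d_nm, 12.6, tolerance = 1e-3)
    expect_equal(red$sfs$n, 1:6)
    expect_equal(red$sfs$amplitude, abs(sfs$F), tolerance = 1e-3)
  }
})

test_that("round trip undoes a nonzero absorption correction", {
  cfg <- noiseless_config(extra_peaks = no_extras(), mu_per_mm = 3,
                          thickness_mm = 0.03, wavelength_nm = 0.3)
  sfs <- profile_to_structure_factors(prot_model(), 100)
  pat <- synthesize_pattern(sfs, config = cfg)
  red <- reduce_pattern(pat, mu_per_mm = 3, thickness_mm = 0.03,
                        wavelength_nm = 0.3)
  expect_equal(red$sfs$amplitude, abs(sfs$F), tolerance = 1e-3)
  # ignoring absorption leaves a visible bias
  red0 <- reduce_pattern(pat)
  expect_gt(max(abs(red0$sfs$amplitude - abs(sfs$F)) / abs(sfs$F)), 1e-3)
})

test_that("reduction is robust to the CHOL and impurity reflections", {
  sfs <- profile_to_structure_factors(prot_model(), 100)
  red_clean <- reduce_pattern(synthesize_pattern(
    sfs, config = noiseless_config(extra_peaks = no_extras())))
  red_chol <- reduce_pattern(synthesize_pattern(
    sfs, config = noiseless_config()))
  expect_equal(red_chol$sfs$amplitude, red_clean$sfs$amplitude,
               tolerance = 5e-3)
  expect_true(all(c(1.2, 1.8) %in% round(red_chol$phase$excluded$q, 1)))
})
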