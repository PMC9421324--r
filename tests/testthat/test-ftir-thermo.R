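test_that("self-deconvolution is the identity at enhancement 1", {
  sp <- synthesize_scissoring_spectrum(c(1465, 1469), c(4, 4), c(1, 1),
                                       window = c(1440, 1495))
  out <- self_deconvolve(sp, half_width = 4, enhancement = 1)
  expect_equal(out$absorbance, sp$absorbance, tolerance = 1e-12)
})

test_that("self-deconvolution resolves a merged Lorentzian doublet", {
  sp <- synthesize_scissoring_spectrum(c(1465, 1469), c(4, 4), c(1, 1),
                                       window = c(1400, 1540))
  expect_equal(prominent_maxima(sp$absorbance), 1)
  dec <- self_deconvolve(sp, half_width = 4, enhancement = 2.5)
  expect_equal(prominent_maxima(dec$absorbance), 2)
  i <- which(diff(sign(diff(dec$absorbance))) == -2) + 1
  top <- sort(sp$wavenumber[i[order(-dec$absorbance[i])][1:2]])
  expect_equal(top, c(1465, 1469), tolerance = 0.3)
})

test_that("noise amplification grows monotonically with enhancement", {
  sp <- synthesize_scissoring_spectrum(c(1465, 1469), c(4, 4), c(1, 1),
                                       window = c(1440, 1495))
  set.seed(1)
  noisy <- sp
  noisy$absorbance <- noisy$absorbance + rnorm(nrow(sp), sd = 0.01)
  amp <- vapply(c(1.2, 1.6, 2.0, 2.4), function(K) {
    stats::sd(self_deconvolve(noisy, 4, K)$absorbance -
                self_deconvolve(sp, 4, K)$absorbance)
  }, numeric(1))
  expect_true(all(diff(amp) > 0))
})

test_that("self-deconvolution refuses non-uniform grids", {
  sp <- ftir_spectrum(c(1460, 1461, 1463, 1466, 1470), rep(1, 5))
  expect_error(self_deconvolve(sp), "non-uniform")
})

mk_stretch_spec <- function(temp, pos) {
  x <- seq(2840, 2860, by = 0.5)
  ftir_spectrum(x, 0.02 + exp(-(x - pos)^2 / 8), temperature_C = temp)
}

test_that("band tracking recovers constant, stepped and ramped positions", {
  temps <- seq(10, 90, by = 2)
  const <- track_band_position(lapply(temps, mk_stretch_spec, pos = 2849.3),
                               c(2845, 2855), temperatures = temps)
  expect_equal(const$wavenumber, rep(2849.3, length(temps)), tolerance = 1e-6)

  pos_step <- 2849 + ifelse(temps >= 37.5, 1, 0)
  stepped <- track_band_position(Map(mk_stretch_spec, temps, pos_step),
                                 c(2845, 2855))
  expect_equal(stepped$wavenumber, pos_step, tolerance = 0.05)

  pos_ramp <- 2849 + 3.5 / (1 + exp(-(temps - 71.2) / 1.5))
  ramp <- track_band_position(Map(mk_stretch_spec, temps, pos_ramp),
                              c(2845, 2855))
  expect_lt(max(abs(ramp$wavenumber - pos_ramp)), 0.05)
})

test_that("band tracking is invariant to uniform absorbance scaling", {
  temps <- seq(10, 50, by = 5)
  specs <- lapply(temps, mk_stretch_spec, pos = 2850.4)
  specs10 <- lapply(specs, function(s) {
    s$absorbance <- s$absorbance * 10
    s
  })
  t1 <- track_band_position(specs, c(2845, 2855), temperatures = temps)
  t2 <- track_band_position(specs10, c(2845, 2855), temperatures = temps)
  expect_equal(t1$wavenumber, t2$wavenumber, tolerance = 1e-12)
})

test_that("transition midpoint recovers the generating sigmoid midpoint", {
  tm <- transition_midpoint(synthesize_thermo_trace())
  expect_false(tm$no_transition)
  expect_equal(tm$T_M_C, 71.2, tolerance = 0.5)
  expect_lt(tm$plateau_low, tm$plateau_high)

  flat <- transition_midpoint(synthesize_thermo_trace(step_heights = c(0, 0)))
  expect_true(flat$no_transition)
})

test_that("T_M estimation is nearly unbiased under noise", {
  tms <- vapply(1:100, function(s) {
    transition_midpoint(synthesize_thermo_trace(noise_sd = 0.1,
                                                seed = s))$T_M_C
  }, numeric(1))
  expect_lt(abs(mean(tms) - 71.2), 0.3)
})

test_that("T_M is equivariant under temperature shifts", {
  t1 <- transition_midpoint(synthesize_thermo_trace())$T_M_C
  t2 <- transition_midpoint(
    synthesize_thermo_trace(temperatures = 10:90 + 4,
                            midpoints = c(37, 71.2) + 4))$T_M_C
  expect_equal(t2 - t1, 4, tolerance = 1e-9)
})

test_that("scissoring triplet fit recovers construction parameters", {
  sp <- synthesize_scissoring_spectrum(c(1463, 1467, 1473), c(1.2, 1.5, 1.2),
                                       c(1, 0.3, 0.95))
  f <- fit_scissoring_triplet(sp, "dCH2")
  expect_false(f$undefined)
  expect_equal(f$splitting_cm, 10, tolerance = 1e-3)
  expect_equal(f$or_mid_ratio, mean(c(1, 0.95)) / 0.3, tolerance = 1e-3)

  spd <- synthesize_scissoring_spectrum(c(1086, 1088.5, 1091),
                                        c(0.9, 1.1, 0.9), c(0.8, 0.23, 0.78))
  fd <- fit_scissoring_triplet(spd, "dCD2")
  expect_equal(fd$splitting_cm, 5, tolerance = 1e-3)
})

test_that("triplet parameter recovery holds at 0.5% noise over seeds", {
  centers <- c(1463, 1467, 1473)
  heights <- c(1, 0.3, 0.95)
  for (s in 1:10) {
    sp <- synthesize_scissoring_spectrum(centers, c(1.2, 1.5, 1.2), heights,
                                         noise_sd = 0.005, seed = s)
    f <- fit_scissoring_triplet(sp, "dCH2")
    expect_false(f$undefined)
    expect_lt(max(abs(f$components$center - centers)), 0.05)
    expect_lt(max(abs(f$components$height - heights) / heights), 0.02)
  }
})

test_that("a single-component band reports undefined splitting", {
  sp <- synthesize_scissoring_spectrum(1467, 1.5, 1)
  f <- fit_scissoring_triplet(sp, "dCH2")
  expect_true(f$undefined)
  expect_true(is.na(f$splitting_cm))
  expect_match(f$reason, ".")
})

test_that("peak-ratio t tests match the closed form and conventions", {
  # identical degenerate groups: P = 1
  same <- compare_peak_ratios(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  # summary-statistics groups: t ~ 3.1, P < 0.05
  tt <- t_test_from_summary(3.5, 0.1, 3, 3.1, 0.2, 3)
  expect_equal(tt$t, 3.098, tolerance = 1e-3)
  expect_lt(tt$p_value, 0.05)
  # swap symmetry
  ts <- t_test_from_summary(3.1, 0.2, 3, 3.5, 0.1, 3)
  expect_equal(ts$t, -tt$t, tolerance = 1e-12)
  expect_equal(ts$p_value, tt$p_value, tolerance = 1e-12)
  # sample-based test agrees with stats::t.test
  set.seed(3)
  a <- rnorm(5, 3.5, 0.1); b <- rnorm(5, 3.1, 0.2)
  mine <- compare_peak_ratios(a, b)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
})
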