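# contrast series straight from forward-model truth (no peak fitting)
truth_series <- function(model, fractions = c(8, 50, 100), id = "truth") {
  sfs <- lapply(fractions, function(fr) {
    s <- profile_to_structure_factors(model, fr)
    s$F <- abs(s$F)        # amplitudes only, as measured
    s$amplitude <- abs(s$amplitude)
    s
  })
  names(sfs) <- as.character(fractions)
  build_contrast_series(sfs, sample_id = id)
}

test_that("regression reproduces an exactly linear series", {
  ser <- truth_series(prot_model())
  ser <- fit_contrast_regression(ser, signs = c(-1, 1, -1, 1, -1, 1))
  expect_equal(ser$regressions$r_squared, rep(1, 6), tolerance = 1e-9)
  # signed slope equals the construction slope: sign_n (|F100|-|F8|)/92
  s8 <- profile_to_structure_factors(prot_model(), 8)
  s100 <- profile_to_structure_factors(prot_model(), 100)
  expect_equal(ser$regressions$slope,
               c(-1, 1, -1, 1, -1, 1) * (abs(s100$F) - abs(s8$F)) / 92,
               tolerance = 1e-9)
})

test_that("slope signs survive 1% noise when |slope|/SE > 3", {
  # Monte-Carlo: 3 fractions, per-order linear truth, multiplicative noise
  set.seed(2024)
  fr <- c(8, 50, 100)
  true_slope <- 0.01
  intercept <- 0.5
  hits <- 0; n_informative <- 0
  for (r in 1:1000) {
    y <- (intercept + true_slope * fr) * (1 + 0.01 * rnorm(3))
    fit <- lm(y ~ fr)
    sl <- coef(fit)[2]
    se <- sqrt(diag(vcov(fit)))[2]
    if (is.finite(se) && abs(sl) / se > 3) {
      n_informative <- n_informative + 1
      hits <- hits + (sign(sl) == sign(true_slope))
    }
  }
  expect_gt(n_informative, 500)
  expect_gte(hits / n_informative, 0.99)
})

test_that("water phases of the trilayer geometry come out - + - + - +", {
  ser <- truth_series(prot_model())
  w <- assign_water_phases(ser)
  expect_equal(w$signs, c(-1L, 1L, -1L, 1L, -1L, 1L))
  expect_false(any(w$diagnostics$ambiguous))
})

test_that("water phases match the analytic transform for water-only models", {
  # water bands at the head-group planes: an inner plane plus the unit-cell
  # boundary, as in any lamellar phase
  for (pos in list(c(1.5, 6.3), c(2.8, 6.3), c(3.5, 6.3))) {
    m <- trilayer_model(headgroup_amplitude = 0, baseline_sld = 0,
                        water_positions_nm = pos, water_sigma_nm = 0.5,
                        water_amplitude = 2)
    analytic <- gaussian_pair_F(1:6, pos[1], 0.5, 1, 12.6) +
      gaussian_pair_F(1:6, pos[2], 0.5, 1, 12.6)
    w <- assign_water_phases(truth_series(m))
    informative <- !w$diagnostics$ambiguous
    expect_gt(sum(informative), 3)
    expect_equal(w$signs[informative],
                 as.integer(sign(analytic))[informative])
  }
})

test_that("zero water amplitude leaves every order ambiguous", {
  w <- assign_water_phases(truth_series(trilayer_model(water_amplitude = 0)))
  expect_true(all(is.na(w$signs)))
  expect_true(all(w$diagnostics$ambiguous))
})

test_that("water phasing requires the 8% and 100% extremes", {
  m <- prot_model()
  sfs <- lapply(c(8, 50), function(fr) profile_to_structure_factors(m, fr))
  names(sfs) <- c("8", "50")
  ser <- build_contrast_series(sfs)
  expect_error(assign_water_phases(ser), "extremes")
})

test_that("sample phases equal water phases when no line crosses zero", {
  ser <- truth_series(prot_model())
  w <- assign_water_phases(ser)
  s <- assign_sample_phases(ser, w)
  expect_equal(s$signs, w$signs)
  expect_false(any(s$diagnostics$flipped))
})

test_that("the crossing rule flips the first order to give + + - + - +", {
  ser <- truth_series(d47_model())
  w <- assign_water_phases(ser)
  expect_equal(w$signs, c(-1L, 1L, -1L, 1L, -1L, 1L))
  s <- assign_sample_phases(ser, w)
  expect_equal(s$signs, c(1L, 1L, -1L, 1L, -1L, 1L))
  expect_true(s$diagnostics$flipped[1])
  expect_true(s$diagnostics$crossing_fraction[1] > 8 &&
                s$diagnostics$crossing_fraction[1] < 100)
  expect_false(any(s$diagnostics$flipped[-1]))
})

test_that("sample phasing recovers forward-model ground truth signs", {
  for (mk in list(prot_model, d7_model, d47_model)) {
    m <- mk()
    truth8 <- sign(profile_to_structure_factors(m, 8)$F)
    ser <- truth_series(m)
    s <- assign_sample_phases(ser, assign_water_phases(ser))
    expect_equal(s$signs, as.integer(truth8))
  }
})

test_that("ambiguous water orders propagate to the sample assignment", {
  ser <- truth_series(d47_model())
  w <- assign_water_phases(ser)
  w$signs[3] <- NA
  s <- assign_sample_phases(ser, w)
  expect_true(is.na(s$signs[3]))
  expect_match(s$diagnostics$reason[3], "ambiguous")
})

test_that("phase signs are invariant to overall intensity scaling", {
  m <- d47_model()
  mk_ser <- function(scale) {
    sfs <- lapply(c(8, 50, 100), function(fr) {
      s <- profile_to_structure_factors(m, fr)
      structure_factor_set(s$n, abs(s$F) * scale, d_nm = attr(s, "d_nm"),
                           d2o_fraction = fr)
    })
    names(sfs) <- c("8", "50", "100")
    build_contrast_series(sfs)
  }
  s1 <- assign_sample_phases(mk_ser(1), assign_water_phases(mk_ser(1)))
  s2 <- assign_sample_phases(mk_ser(250), assign_water_phases(mk_ser(250)))
  expect_equal(s1$signs, s2$signs)
})

test_that("flipping the water amplitude flips the water-component signs", {
  m_pos <- trilayer_model(water_amplitude = 2.5)
  m_neg <- trilayer_model(water_amplitude = -2.5)
  Fpos <- profile_to_structure_factors(m_pos, 100)$F -
    profile_to_structure_factors(m_pos, 8)$F
  Fneg <- profile_to_structure_factors(m_neg, 100)$F -
    profile_to_structure_factors(m_neg, 8)$F
  expect_equal(sign(Fpos), -sign(Fneg))
})

test_that("assigned signs minimize L2 distance to the true density", {
  m <- d47_model()
  fr <- 8
  sfs_true <- profile_to_structure_factors(m, fr)
  ser <- truth_series(m)
  s <- assign_sample_phases(ser, assign_water_phases(ser))
  x <- seq(-6.3, 6.3, length.out = 241)
  rho_true <- model_density(m, x, fr)
  amp <- abs(sfs_true$F)
  combos <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6)))
  l2 <- apply(combos, 1, function(sv) {
    rho <- attr(sfs_true, "F0") +
      2 * colSums(sv * amp * t(outer(x, 1:6, function(x, n)
        cos(2 * pi * n * x / 12.6))))
    sum((rho - rho_true)^2)
  })
  expect_equal(as.integer(combos[which.min(l2), ]), s$signs)
})
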