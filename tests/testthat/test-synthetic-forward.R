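test_that("bare model density reduces to the baseline", {
  m <- trilayer_model(headgroup_amplitude = 0, water_amplitude = 0,
                      baseline_sld = -0.3)
  x <- seq(-6.3, 6.3, length.out = 101)
  expect_equal(model_density(m, x, 100), rep(-0.3, 101))
})

test_that("model density is even in x for random models", {
  set.seed(11)
  for (rep in 1:5) {
    m <- trilayer_model(
      headgroup_positions_nm = sort(runif(2, 0.5, 6.3)),
      headgroup_sigma_nm = runif(1, 0.2, 0.6),
      labels = data.frame(center_nm = runif(1, 0, 5),
                          sigma_nm = runif(1, 0.3, 1),
                          amplitude = runif(1, 0.5, 3)),
      water_amplitude = runif(1, 0, 3))
    x <- runif(1000, 0, 6.3)
    expect_equal(model_density(m, x, 50), model_density(m, -x, 50),
                 tolerance = 1e-14)
  }
})

test_that("positions outside the unit cell are rejected", {
  expect_error(trilayer_model(headgroup_positions_nm = c(2.2, 7.0)),
               "outside the unit cell")
  expect_error(
    trilayer_model(labels = data.frame(center_nm = -8, sigma_nm = 0.5,
                                       amplitude = 1)),
    "outside the unit cell")
})

test_that("water term peaks at the four head-group planes at 100% D2O", {
  m <- trilayer_model()
  x <- seq(-6.3, 6.3, by = 0.001)
  water <- model_density(m, x, 100) - model_density(m, x, 8)
  i <- which(diff(sign(diff(water))) == -2) + 1
  # boundary maximum sits at the grid ends under periodicity
  pos <- sort(unique(round(c(abs(x[i]),
                             if (water[1] >= max(water) * 0.5) 6.3), 2)))
  expect_equal(pos, c(2.20, 6.30), tolerance = 0.02)
})

test_that("structure factors match quadrature and trivial identities", {
  m0 <- trilayer_model(headgroup_amplitude = 0, water_amplitude = 0,
                       baseline_sld = 1.7)
  sfs <- profile_to_structure_factors(m0, 8, n_orders = 4)
  expect_equal(attr(sfs, "F0"), 1.7, tolerance = 1e-10)
  expect_equal(sfs$F, rep(0, 4), tolerance = 1e-12)

  # random even profile vs the analytic Gaussian-pair transform
  m <- trilayer_model(water_amplitude = 0,
                      labels = data.frame(center_nm = 3.1, sigma_nm = 0.7,
                                          amplitude = 2.2))
  sfs <- profile_to_structure_factors(m, 8, n_orders = 6)
  d <- 12.6
  analytic <- gaussian_pair_F(1:6, 3.1, 0.7, 2.2, d) +
    gaussian_pair_F(1:6, 2.2, 0.35, 1.4, d) +
    gaussian_pair_F(1:6, 6.3, 0.35, 1.4, d)
  expect_equal(sfs$F, analytic, tolerance = 1e-6)
})

test_that("Simpson coefficients agree with adaptive quadrature", {
  set.seed(4)
  m <- trilayer_model(labels = data.frame(center_nm = runif(1, 0, 5),
                                          sigma_nm = 0.8, amplitude = 2))
  sfs <- profile_to_structure_factors(m, 50, n_orders = 8)
  d <- 12.6
  oracle <- vapply(1:8, function(n) {
    2 / d * stats::integrate(function(x)
      model_density(m, x, 50) * cos(2 * pi * n * x / d),
      -d / 2, d / 2, rel.tol = 1e-10, subdivisions = 500L)$value
  }, numeric(1))
  expect_equal(sfs$F, oracle, tolerance = 1e-8)
  F0_oracle <- stats::integrate(function(x) model_density(m, x, 50),
                                -d / 2, d / 2, rel.tol = 1e-10)$value / d
  expect_equal(attr(sfs, "F0"), F0_oracle, tolerance = 1e-8)
})

test_that("synthesized patterns are deterministic given the seed", {
  cfg <- sim_config(noise_fraction = 0.02, seed = 99)
  sfs <- profile_to_structure_factors(prot_model(), 100)
  p1 <- synthesize_pattern(sfs, config = cfg)
  p2 <- synthesize_pattern(sfs, config = cfg)
  expect_identical(p1$intensity, p2$intensity)
  p3 <- synthesize_pattern(sfs, config = cfg, seed = 100)
  expect_false(identical(p1$intensity, p3$intensity))
})

test_that("contrast series is linear in the buffer mix with retained truth", {
  cfg <- noiseless_config()
  bun <- synthesize_contrast_series(prot_model(), cfg)
  expect_named(bun$truth, c("8", "50", "100"))
  w50 <- water_contrast_weight(50)
  for (n in 1:6) {
    F8 <- bun$truth[["8"]]$F[n]
    F50 <- bun$truth[["50"]]$F[n]
    F100 <- bun$truth[["100"]]$F[n]
    expect_equal(F50, F8 + w50 * (F100 - F8), tolerance = 1e-9)
  }
  # zero water amplitude: identical F across fractions
  m0 <- trilayer_model(water_amplitude = 0)
  b0 <- synthesize_contrast_series(m0, cfg)
  expect_equal(b0$truth[["8"]]$F, b0$truth[["100"]]$F, tolerance = 1e-12)
  # single fraction is rejected: phasing impossible
  expect_error(synthesize_contrast_series(prot_model(),
                                          sim_config(d2o_fractions = 100)),
               "two distinct")
})

test_that("ground-truth water signs alternate for the trilayer geometry", {
  m <- trilayer_model(headgroup_amplitude = 0, baseline_sld = 0)
  sfs <- profile_to_structure_factors(m, 100)
  analytic <- gaussian_pair_F(1:6, 2.2, 0.6, 1, 12.6) +
    gaussian_pair_F(1:6, 6.3, 0.6, 1, 12.6)
  expect_equal(sign(sfs$F), sign(analytic))
  expect_equal(sign(sfs$F), c(-1, 1, -1, 1, -1, 1))
})

test_that("thermo trace generator honours its stated transitions", {
  flat <- synthesize_thermo_trace(step_heights = c(0, 0))
  expect_equal(diff(range(flat$wavenumber)), 0)
  tr1 <- synthesize_thermo_trace(noise_sd = 0.05, seed = 5)
  tr2 <- synthesize_thermo_trace(noise_sd = 0.05, seed = 5)
  expect_identical(tr1$wavenumber, tr2$wavenumber)
  expect_error(synthesize_thermo_trace(temperatures = c(10, 9, 11)),
               "strictly increasing")
})

test_that("scissoring generator validates its window and keeps truth", {
  expect_error(synthesize_scissoring_spectrum(1500, 1, 1,
                                              window = c(1455, 1480)),
               "window")
  sp <- synthesize_scissoring_spectrum(c(1463, 1467, 1473), c(1, 1, 1),
                                       c(1, 0.3, 1))
  expect_equal(attr(sp, "truth")$centers, c(1463, 1467, 1473))
  s1 <- synthesize_scissoring_spectrum(1467, 1.5, 1, noise_sd = 0.01, seed = 2)
  s2 <- synthesize_scissoring_spectrum(1467, 1.5, 1, noise_sd = 0.01, seed = 2)
  expect_identical(s1$absorbance, s2$absorbance)
})
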