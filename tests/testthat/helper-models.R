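# Shared fixtures: the three study-condition unit-cell models and a
# noise-free simulation config.

prot_model <- function() trilayer_model()

# terminally deuterated sphingosine chain (d7): small label at +/- 4.2 nm
d7_model <- function() {
  trilayer_model(labels = data.frame(center_nm = 4.2, sigma_nm = 0.6,
                                     amplitude = 0.5))
}

# perdeuterated acyl chain (d47): strong central label plus a boundary
# fraction; constructed so the first-order structure factor is positive at
# the 8% null contrast (zero-crossing sign flip)
d47_model <- function() {
  trilayer_model(labels = data.frame(center_nm = c(0, 6.3),
                                     sigma_nm = c(0.9, 0.6),
                                     amplitude = c(3, 0.8)))
}

noiseless_config <- function(...) sim_config(noise_fraction = 0, ...)

no_extras <- function() {
  data.frame(q_nm = numeric(0), intensity = numeric(0))
}

# signed Fourier coefficients of a mirrored Gaussian pair, analytic
# (independent of the package's quadrature path)
gaussian_pair_F <- function(n, center, sigma, amp, d) {
  2 / d * amp * sigma * sqrt(2 * pi) *
    exp(-2 * pi^2 * n^2 * sigma^2 / d^2) *
    (if (abs(center) < 1e-12) 1 else 2 * cos(2 * pi * n * center / d))
}

# count local maxima above a fraction of the tallest
prominent_maxima <- function(y, frac = 0.2) {
  i <- which(diff(sign(diff(y))) == -2) + 1
  sum(y[i] > frac * max(y))
}
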