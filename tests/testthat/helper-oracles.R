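# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: quadrature for the IRF convolution, an ODE
# integrator for the cascade, dense-grid evaluation for spectra.

# Brute-force convolution of exp(-s/tau) (s >= 0) with a Gaussian of width
# sigma centred at mu, by adaptive quadrature.
conv_quadrature <- function(t, tau, mu = 0, sigma = 0) {
  vapply(t, function(tt) {
    stats::integrate(function(s) exp(-s / tau) * stats::dnorm(tt - mu - s, 0, sigma),
                     lower = 0, upper = Inf, rel.tol = 1e-12)$value
  }, numeric(1))
}

# Gaussian band evaluated on an arbitrary grid (independent of eval_bands).
gauss_band <- function(wl, center, sigma_nm, amplitude = 1) {
  amplitude * exp(-(wl - center)^2 / (2 * sigma_nm^2))
}

# Small two-component ground truth used by several fitting tests.
toy_truth <- function(noise_scale = 0, lifetimes = c(10.5, 45.5),
                      rel_amplitude = c(0.4, 0.6)) {
  kinetic_ground_truth(
    lifetimes = lifetimes,
    das_shapes = default_das_shapes(rel_amplitude,
                                    centers = c(687, 690)[seq_along(lifetimes)],
                                    fwhms = c(28, 24)[seq_along(lifetimes)]),
    noise_scale = noise_scale
  )
}

# Ground truth matching the published alpha-DM solution.
alpha_truth <- function(noise_scale = 0.02) {
  comp <- psi_lhc_kinetics("alpha")
  kinetic_ground_truth(lifetimes = comp$lifetime,
                       das_shapes = default_das_shapes(comp$rel_amplitude),
                       noise_scale = noise_scale,
                       fixed = comp$fixed)
}
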