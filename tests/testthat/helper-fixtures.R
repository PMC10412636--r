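# shared fixtures, all generated in code

# constant-rate Poisson photon stream (no intensity fluctuations)
make_poisson_stream <- function(rate, duration, seed,
                                pulse_period_ns = 25) {
  with_seed(seed, {
    n <- rpois(1, rate * duration)
    photon_stream(sort(runif(n, 0, duration)),
                  runif(n, 0, pulse_period_ns),
                  meta = list(duration = duration,
                              pulse_period_ns = pulse_period_ns))
  })
}

# small, fast Brownian-dynamics simulation (tD = 1 ms)
small_sim <- function(seed, concentration = 1e-9, duration = 6,
                      brightness = 3e4) {
  gen_fcs_photon_stream(fcs_sim_params(
    concentration = concentration, w0 = 0.35, kappa = 5,
    diffusion_coeff = 30.625, box_side = 3.5,
    brightness = brightness, duration = duration, dt = 5e-5,
    seed = seed))
}

# Gaussian emission band sampled on a 1 nm grid
make_emission <- function(center = 345, fwhm = 60, height = 100,
                          from = 286, to = 460, by = 1, offset = 0) {
  wl <- seq(from + offset, to, by = by)
  emission_spectrum(wl, height * exp(-4 * log(2) * (wl - center)^2 / fwhm^2))
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
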