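test_that("quenching generator reproduces the three quenching laws exactly", {
  # K_SV * Q = 1 halves the intensity
  tr <- quench_ground_truth("stern_volmer", F0 = 100, K_SV = 1e4)
  s <- gen_quenching_titration(tr, 1e-4)
  expect_equal(s$F, 50)

  # power-law model with n = 1 coincides with Stern-Volmer
  q <- seq(1e-5, 3e-4, length.out = 12)
  s_sv <- gen_quenching_titration(tr, q)
  s_pb <- gen_quenching_titration(
    quench_ground_truth("power_binding", F0 = 100, K_b = 1e4, n = 1), q)
  expect_equal(s_pb$F, s_sv$F)

  # partition model follows the hyperbolic quenching law
  trp <- quench_ground_truth("partition", F0 = 100, K_d = 12.97,
                             lip_conc = 0.1)
  sp <- gen_quenching_titration(trp, c(5, 10, 20), unit = "uM")
  expect_equal((100 / sp$F) - 1, 0.1 * c(5, 10, 20) / (12.97 + c(5, 10, 20)))
})

test_that("ground-truth objects demand exactly the model's parameters", {
  expect_error(quench_ground_truth("stern_volmer", F0 = 100),
               class = "configuration_error")
  expect_error(quench_ground_truth("stern_volmer", F0 = 100, K_SV = 1e4,
                                   n = 2),
               class = "configuration_error")
  expect_error(quench_ground_truth("partition", F0 = 100, K_d = 10),
               class = "configuration_error")
  tr <- quench_ground_truth("stern_volmer", F0 = 100, K_SV = 1e4)
  expect_error(gen_quenching_titration(tr, c(0, 1e-4)),
               class = "validation_error")
  expect_error(gen_quenching_titration(tr, c(2e-4, 1e-4)),
               class = "validation_error")
})

test_that("seeded generation is bit-identical and noise has the requested CV", {
  tr <- quench_ground_truth("stern_volmer", F0 = 100, K_SV = 1e4,
                            noise_cv = 0.05, seed = 11)
  q <- seq(1e-5, 3e-4, length.out = 10)
  expect_identical(gen_quenching_titration(tr, q, replicates = 3L),
                   gen_quenching_titration(tr, q, replicates = 3L))

  # empirical CV of the multiplicative noise matches the request
  tr2 <- quench_ground_truth("stern_volmer", F0 = 100, K_SV = 1e4,
                             noise_cv = 0.05, seed = 4)
  s <- gen_quenching_titration(tr2, 1e-4, replicates = 4000L)
  expect_equal(sd(s$F) / mean(s$F), 0.05, tolerance = 0.1)
  expect_equal(mean(s$F), 50, tolerance = 0.01)

  s1 <- gen_ftir_spectrum(list(band_spec(1062, 8, 1)), c(1040, 1110, 0.5),
                          noise_sd = 0.01, seed = 3)
  s2 <- gen_ftir_spectrum(list(band_spec(1062, 8, 1)), c(1040, 1110, 0.5),
                          noise_sd = 0.01, seed = 3)
  expect_identical(s1, s2)
})

test_that("polarized readings invert the anisotropy formula", {
  r <- gen_polarized_readings(0, total_I = 3, G = 1)
  expect_equal(r$I_par, 1)
  expect_equal(r$I_perp, 1)
  expect_equal(compute_anisotropy(gen_polarized_readings(0.4, G = 1)), 0.4)
  # total intensity constraint holds at any G
  r2 <- gen_polarized_readings(0.13, total_I = 7, G = 1.2)
  expect_equal(r2$I_par + 2 * 1.2 * r2$I_perp, 7)
  expect_error(gen_polarized_readings(1.2), class = "validation_error")
})

test_that("noisy polarized readings recover the true anisotropy on average", {
  # Monte Carlo: mean recovered A over many noisy replicates within 3 SE
  a_hat <- vapply(1:1000, function(s) {
    mean(compute_anisotropy(gen_polarized_readings(
      0.13, G = 1.2, noise_cv = 0.02, n = 10L, seed = s)))
  }, 0)
  se <- sd(a_hat) / sqrt(length(a_hat))
  expect_lt(abs(mean(a_hat) - 0.13), 3 * se + 1e-4)
})

test_that("analytic correlation curves satisfy the model's limits", {
  lags <- log_lags(1e-7, 10)
  cu <- gen_correlation_curve(N = 5, tD = 0.07, kappa = 5, lags = lags)
  # amplitude identity: G -> 1/N as tau -> 0
  expect_equal(cu$G[1], 1 / 5, tolerance = 1e-4)
  # half amplitude at tau = tD in the 2D (kappa -> infinity) limit
  cu2 <- gen_correlation_curve(N = 5, tD = 0.07, kappa = 1e6,
                               lags = c(0.07, 0.14))
  expect_equal(cu2$G[1], 1 / (2 * 5), tolerance = 1e-6)
})

test_that("photon-stream simulator honours its physical contracts", {
  # zero brightness and background: empty stream
  p0 <- fcs_sim_params(concentration = 1e-9, box_side = 3.5, w0 = 0.35,
                       kappa = 5, diffusion_coeff = 30.625,
                       brightness = 0, duration = 1, dt = 5e-5, seed = 1)
  expect_length(gen_fcs_photon_stream(p0)$macro_times, 0)

  # expected particle number in the effective volume: closed form
  expect_equal(expected_particle_number(1e-9, 0.35, 5), 0.72,
               tolerance = 0.01)

  # invalid configurations are rejected
  expect_error(fcs_sim_params(1e-9, w0 = 0.35, box_side = 1),
               class = "configuration_error")
  expect_error(fcs_sim_params(1e-9, w0 = 0.35, diffusion_coeff = 30.625,
                              dt = 1e-2),
               class = "configuration_error")

  # seeded simulation is bit-identical
  p <- fcs_sim_params(concentration = 1e-9, box_side = 3.5, w0 = 0.35,
                      kappa = 5, diffusion_coeff = 30.625,
                      brightness = 1e4, duration = 0.5, dt = 5e-5, seed = 8)
  expect_identical(gen_fcs_photon_stream(p), gen_fcs_photon_stream(p))
})

test_that("simulated count rate matches brightness x mean profile x particles", {
  # expected rate: brightness * (integral of the detection profile over
  # the box / box volume) * n_particles + background
  w0 <- 0.35; kappa <- 5; sides <- c(3.5, 3.5, 17.5)
  profile_integral <- (pi / 2)^1.5 * w0^3 * kappa   # um^3
  sims <- lapply(1:12, small_sim, duration = 2)
  rates <- vapply(sims, function(st) length(st$macro_times) / 2, 0)
  expected <- 3e4 * profile_integral / prod(sides) * sims[[1]]$meta$n_particles
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - expected), 3 * se)
})
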