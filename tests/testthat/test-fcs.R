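test_that("a constant-rate Poisson stream is uncorrelated", {
  st <- make_poisson_stream(rate = 5e4, duration = 10, seed = 3)
  cu <- correlate(st, "multi_tau", bin_width = 1e-4)
  # G should scatter around 0 within shot noise; 3 SE of the scatter
  expect_lt(abs(mean(cu$G)), 3 * sd(cu$G) / sqrt(length(cu$G)))
  expect_lt(max(abs(cu$G)), 0.02)
})

test_that("correlator input contracts are enforced", {
  empty <- photon_stream(numeric(0), numeric(0), meta = list(duration = 1))
  expect_error(correlate(empty, "direct", bin_width = 1e-4),
               class = "validation_error")
  st <- make_poisson_stream(5e3, 2, seed = 1)
  expect_warning(correlate(st, "multi_tau", bin_width = 1e-4, max_lag = 1),
                 "truncated")
})

test_that("multi-tau and brute-force correlators agree on a test stream", {
  st <- small_sim(seed = 13, concentration = 4e-10, duration = 10,
                  brightness = 2e5)
  mt <- correlate(st, "multi_tau", bin_width = 1e-4, max_lag = 5e-3)
  dc <- correlate(st, "direct", bin_width = 1e-4, lags = mt$lags,
                  max_lag = 5e-3)
  gm <- mt$G[match(round(dc$lags, 12), round(mt$lags, 12))]
  expect_true(all(is.finite(gm)))
  expect_lt(max(abs(gm - dc$G) / abs(dc$G)), 0.02)
})

test_that("diffusion fit recovers analytic curves and separates parameters", {
  lags <- log_lags(1e-6, 10)
  # the relaxed-plasmid state: N = 5, tD = 70 ms
  fit <- fit_diffusion_model(gen_correlation_curve(5, 0.07, 5, lags),
                             kappa = 5)
  expect_true(fit$converged)
  expect_equal(fit$PN, 5, tolerance = 1e-3)
  expect_equal(fit$tD, 0.07, tolerance = 1e-3)

  # the folded endpoint: tD = 3.5 ms
  fit2 <- fit_diffusion_model(gen_correlation_curve(0.7, 3.5e-3, 5, lags),
                              kappa = 5)
  expect_equal(fit2$tD, 3.5e-3, tolerance = 1e-3)
  expect_equal(fit2$PN, 0.7, tolerance = 1e-3)

  # halving the amplitude doubles PN and leaves tD unchanged
  cu <- gen_correlation_curve(5, 0.07, 5, lags)
  cu$G <- cu$G / 2
  fit3 <- fit_diffusion_model(cu, kappa = 5)
  expect_equal(fit3$PN, 10, tolerance = 1e-3)
  expect_equal(fit3$tD, 0.07, tolerance = 1e-3)

  # stderr-weighted fits are supported
  cun <- gen_correlation_curve(5, 0.07, 5, lags, noise_sd = 1e-3, seed = 2)
  fit4 <- fit_diffusion_model(cun, kappa = 5)
  expect_true(fit4$converged)
  expect_lt(rel_err(fit4$tD, 0.07), 0.05)
})

test_that("stream-level simulation round trip recovers N and tD within 10%", {
  # single-measurement scatter of tD is a few percent per 20 s of
  # averaging; the 10% contract is checked on the mean of 4 seeds
  tds <- numeric(4); pns <- numeric(4)
  for (s in seq_along(tds)) {
    st <- small_sim(seed = 100 + s, duration = 20)
    cu <- correlate(st, "multi_tau", bin_width = 1e-5)
    fit <- fit_diffusion_model(cu, kappa = 5)
    tds[s] <- fit$tD; pns[s] <- fit$PN
  }
  expect_lt(rel_err(mean(tds), 1e-3), 0.10)
  expect_lt(rel_err(mean(pns), 0.719), 0.10)
})

test_that("lifetime MLE recovers mono-exponential decays", {
  # pure decays at the unquenched and quenched lifetimes
  for (tau in c(4.25, 2.3)) {
    mt <- with_seed(17, rexp(1e5, 1 / tau) %% 25)
    fit <- fit_lifetime(mt, 25, fit_window_start = 0.5)
    expect_lt(abs(fit$tau - tau), 0.05)
  }
  # 50% uniform background: tau within 3 SE
  mt <- with_seed(31, c(rexp(5e4, 1 / 4) %% 25, runif(5e4, 0, 25)))
  fit <- fit_lifetime(mt, 25)
  expect_lt(abs(fit$tau - 4), 3 * fit$se_tau)
  expect_equal(fit$background, 0.5, tolerance = 0.15)
  expect_error(fit_lifetime(rexp(100, 1 / 4), 25),
               class = "insufficient_data_error")
})

test_that("lifetime estimator is nearly unbiased at 1e5 photons", {
  taus <- vapply(1:15, function(s) {
    mt <- with_seed(s, rexp(1e5, 1 / 4.25) %% 25)
    fit_lifetime(mt, 25, fit_window_start = 0.5)$tau
  }, 0)
  expect_lt(abs(mean(taus) - 4.25), 0.02)
})

test_that("expected particle number is the linear Gaussian-volume calibration", {
  pn <- expected_particle_number(1e-9, 0.35, 5)
  expect_equal(pn, 0.72, tolerance = 0.01)
  expect_equal(expected_particle_number(2e-9, 0.35, 5), 2 * pn)
  expect_equal(expected_particle_number(0, 0.35, 5), 0)
})

test_that("folding classification follows the PN calibration", {
  expect_identical(classify_folding(0.7, 0.7), "folded")
  expect_identical(classify_folding(5, 0.7), "relaxed")
  expect_identical(classify_folding(1.2, 0.7), "intermediate")
  fake_fit <- structure(list(PN = 0.65), class = "fcs_fit")
  expect_identical(classify_folding(fake_fit, 0.72), "folded")
})
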