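#' Parameters for the Brownian-dynamics FCS photon simulator
#'
#' Describes a confocal FCS measurement: point-like fluorophores at a
#' given molar concentration diffuse through a periodic box and are
#' observed through a 3D Gaussian detection profile
#' `w(r) = exp(-2 (x^2+y^2)/w0^2 - 2 z^2/(kappa w0)^2)`.
#' The implied ground truths are the diffusion time
#' `tD = w0^2 / (4 D)` and the particle number
#' `PN = c * N_A * pi^{3/2} * w0^3 * kappa` (see
#' [expected_particle_number()]).
#'
#' Validity constraints: every box side must be at least `10 * w0` (and
#' the axial side at least `10 * kappa * w0`, enforced automatically
#' when a scalar side is given), the propagation step must satisfy
#' `sqrt(2 D dt) <= w0 / 5`, and the duration must cover at least 100
#' diffusion times.
#'
#' @param concentration molar fluorophore concentration.
#' @param box_side box edge length(s) in micrometers; scalar (the axial
#'   side is then expanded to `10 * kappa * w0` if larger) or length 3
#'   `(x, y, z)`.
#' @param w0 lateral 1/e^2 beam radius, micrometers.
#' @param kappa structure parameter (axial/lateral ratio).
#' @param diffusion_coeff diffusion coefficient, um^2/s.
#' @param brightness photon detection rate at beam center, photons/s.
#' @param lifetime_ns excited-state lifetime, ns.
#' @param background_rate uncorrelated background, photons/s.
#' @param duration measurement length, s.
#' @param dt propagation step, s.
#' @param pulse_period_ns laser pulse period, ns (40 MHz -> 25 ns).
#' @param irf_offset_ns fixed micro-time offset standing in for the
#'   instrument response delay, ns.
#' @param seed optional integer seed.
#' @return an object of class `fcs_sim_params`.
#' @export
fcs_sim_params <- function(concentration, w0 = 0.35, kappa = 5,
                           diffusion_coeff = 30.625,
                           box_side = NULL,
                           brightness = 3e4, lifetime_ns = 4.25,
                           background_rate = 0, duration = 10,
                           dt = 5e-5, pulse_period_ns = 25,
                           irf_offset_ns = 2, seed = NULL) {
  for (nm in c("concentration", "w0", "kappa", "diffusion_coeff",
               "duration", "dt", "pulse_period_ns"))
    if (get(nm) <= 0)
      fb_stop(sprintf("%s must be positive", nm), "configuration_error")
  if (brightness < 0 || background_rate < 0 || irf_offset_ns < 0)
    fb_stop("rates and offsets must be nonnegative", "configuration_error")
  if (is.null(box_side)) box_side <- 10 * w0
  if (length(box_side) == 1)
    box_side <- c(box_side, box_side, max(box_side, 10 * kappa * w0))
  if (length(box_side) != 3)
    fb_stop("box_side must be scalar or length 3", "configuration_error")
  if (any(box_side < 10 * w0))
    fb_stop("every box side must be at least 10 * w0", "configuration_error")
  if (sqrt(2 * diffusion_coeff * dt) > w0 / 5)
    fb_stop("dt too coarse: require sqrt(2 D dt) <= w0/5",
            "configuration_error")
  tD <- w0^2 / (4 * diffusion_coeff)
  if (duration < 100 * tD)
    fb_stop("duration must cover at least 100 diffusion times",
            "configuration_error")
  structure(list(concentration = concentration, box_side = box_side,
                 w0 = w0, kappa = kappa,
                 diffusion_coeff = diffusion_coeff,
                 brightness = brightness, lifetime_ns = lifetime_ns,
                 background_rate = background_rate, duration = duration,
                 dt = dt, pulse_period_ns = pulse_period_ns,
                 irf_offset_ns = irf_offset_ns, seed = seed),
            class = "fcs_sim_params")
}

#' Simulate a TCSPC photon stream from diffusing fluorophores
#'
#' Propagates point emitters by Brownian steps through a periodic box
#' and draws, per time step, Poisson photon counts at the summed
#' detection rate `brightness * sum_i w(r_i)`. Each signal photon
#' carries a micro-time `irf_offset + Exp(lifetime)` folded into the
#' pulse period; background photons are uniform in macro- and
#' micro-time. The returned stream is time-ordered. Seeded runs are
#' bit-reproducible.
#'
#' Triplet blinking, photobleaching, detector afterpulsing and dead
#' time are deliberately not modelled (the analyses downstream assume
#' low-power conditions under which they are negligible).
#'
#' @param params an [fcs_sim_params()] object.
#' @return a [photon_stream()]; its `meta` records the duration, pulse
#'   period, the number of simulated particles and the ground-truth
#'   `tD` and expected particle number.
#' @export
gen_fcs_photon_stream <- function(params) {
  if (!inherits(params, "fcs_sim_params"))
    fb_stop("params must be an fcs_sim_params object", "configuration_error")
  p <- params
  with_seed(p$seed, {
    nsteps <- ceiling(p$duration / p$dt)
    vol_L <- prod(p$box_side) * 1e-15
    npart <- round(p$concentration * AVOGADRO * vol_L)
    wz2 <- (p$kappa * p$w0)^2

    macro <- numeric(0)
    micro <- numeric(0)
    if (p$brightness > 0 && npart > 0) {
      sigma <- sqrt(2 * p$diffusion_coeff * p$dt)
      rate <- numeric(nsteps)
      for (i in seq_len(npart)) {
        dx <- (runif(1) * p$box_side[1] +
                 cumsum(rnorm(nsteps, 0, sigma))) %% p$box_side[1] -
              p$box_side[1] / 2
        dy <- (runif(1) * p$box_side[2] +
                 cumsum(rnorm(nsteps, 0, sigma))) %% p$box_side[2] -
              p$box_side[2] / 2
        dz <- (runif(1) * p$box_side[3] +
                 cumsum(rnorm(nsteps, 0, sigma))) %% p$box_side[3] -
              p$box_side[3] / 2
        rate <- rate + exp(-2 * (dx * dx + dy * dy) / p$w0^2 -
                             2 * dz * dz / wz2)
      }
      counts <- rpois(nsteps, p$brightness * p$dt * rate)
      nph <- sum(counts)
      if (nph > 0) {
        step_of <- rep.int(seq_len(nsteps), counts)
        macro <- (step_of - 1) * p$dt + runif(nph) * p$dt
        micro <- (p$irf_offset_ns + rexp(nph, 1 / p$lifetime_ns)) %%
          p$pulse_period_ns
      }
    }
    if (p$background_rate > 0) {
      nbg <- rpois(1, p$background_rate * p$duration)
      macro <- c(macro, runif(nbg) * p$duration)
      micro <- c(micro, runif(nbg) * p$pulse_period_ns)
    }
    ord <- order(macro)
    photon_stream(
      macro[ord], micro[ord],
      meta = list(duration = p$duration,
                  pulse_period_ns = p$pulse_period_ns,
                  n_particles = npart,
                  tD_true = p$w0^2 / (4 * p$diffusion_coeff),
                  pn_expected = expected_particle_number(
                    p$concentration, p$w0, p$kappa))
    )
  })
}

#' Generate an analytic one-component 3D diffusion correlation curve
#'
#' Evaluates `G(tau) = (1/N) (1 + tau/tD)^-1 (1 + tau/(kappa^2
#' tD))^-1/2` on the given lag grid, optionally adding Gaussian noise.
#' A convenient stand-in for a full photon-stream simulation when only
#' the fitting stage is under study.
#'
#' @param N mean particle number in the effective volume.
#' @param tD diffusion time, seconds.
#' @param kappa structure parameter.
#' @param lags strictly increasing positive lag times, seconds.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed optional integer seed.
#' @return a [correlation_curve()]; `stderr` is set to `noise_sd` when
#'   noise is added.
#' @export
gen_correlation_curve <- function(N, tD, kappa = 5, lags,
                                  noise_sd = 0, seed = NULL) {
  if (N <= 0 || tD <= 0 || kappa <= 0)
    fb_stop("N, tD and kappa must be positive", "validation_error")
  g <- (1 / N) / ((1 + lags / tD) * sqrt(1 + lags / (kappa^2 * tD)))
  if (noise_sd > 0)
    g <- g + with_seed(seed, rnorm(length(lags), 0, noise_sd))
  correlation_curve(lags, g,
                    stderr = if (noise_sd > 0) rep(noise_sd, length(lags)),
                    meta = list(N_true = N, tD_true = tD, kappa = kappa))
}

#' Logarithmically spaced lag grid
#'
#' @param from,to lag range in seconds.
#' @param per_decade points per decade.
#' @return numeric vector of lags.
#' @export
log_lags <- function(from = 1e-6, to = 10, per_decade = 16) {
  10^seq(log10(from), log10(to),
         length.out = ceiling(per_decade * log10(to / from)) + 1)
}
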