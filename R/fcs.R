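#' Intensity autocorrelation of a photon stream
#'
#' Bins the photon macro-times into counts of width `bin_width` and
#' computes the normalized fluctuation autocorrelation
#' `G(tau) = <dI(t) dI(t+tau)> / <I>^2` with symmetric normalization
#' (left and right means computed over the actually overlapping
#' segments, which suppresses drift bias).
#'
#' Two schemes are available:
#' * `"multi_tau"` — the standard quasi-logarithmic correlator: the
#'   first cascade evaluates `2 m` lags at the base bin width, then the
#'   counts are rebinned by 2 and each subsequent cascade evaluates `m`
#'   further lags at the doubled width (`m = channels_per_cascade`).
#' * `"direct"` — exact binned autocorrelation evaluated lag by lag at
#'   the base bin width; the brute-force reference, quadratic-cost but
#'   exact, intended for validation on short streams.
#'
#' @param stream a [photon_stream()].
#' @param scheme `"multi_tau"` or `"direct"`.
#' @param bin_width base bin width, seconds.
#' @param channels_per_cascade lags per multi-tau cascade.
#' @param max_lag largest lag, seconds; defaults to a tenth of the
#'   stream duration and is truncated (with a warning) if requested
#'   larger.
#' @param lags for the direct scheme only: lag times to evaluate
#'   (rounded to multiples of `bin_width`); defaults to a
#'   quasi-logarithmic set.
#' @return a [correlation_curve()]; its `meta` records the scheme, bin
#'   width, duration and mean count rate.
#' @export
correlate <- function(stream, scheme = c("multi_tau", "direct"),
                      bin_width, channels_per_cascade = 8L,
                      max_lag = NULL, lags = NULL) {
  scheme <- match.arg(scheme)
  if (!inherits(stream, "photon_stream"))
    fb_stop("stream must be a photon_stream", "validation_error")
  if (length(stream$macro_times) == 0)
    fb_stop("empty photon stream", "validation_error")
  if (bin_width <= 0)
    fb_stop("bin_width must be positive", "validation_error")
  duration <- stream$meta$duration %||% max(stream$macro_times)
  if (is.null(max_lag)) {
    max_lag <- duration / 10
  } else if (max_lag > duration / 10) {
    warning("max_lag exceeds a tenth of the stream duration; truncated")
    max_lag <- duration / 10
  }
  nb <- ceiling(duration / bin_width)
  idx <- pmin(floor(stream$macro_times / bin_width) + 1L, nb)
  counts <- tabulate(idx, nbins = nb)

  if (scheme == "direct") {
    ks <- if (is.null(lags)) {
      k_max <- floor(max_lag / bin_width)
      unique(pmin(round(10^seq(0, log10(max(k_max, 1)), length.out = 200)),
                  k_max))
    } else {
      sort(unique(round(lags / bin_width)))
    }
    ks <- ks[ks >= 1 & ks < nb]
    G <- vapply(ks, function(k) corr_at_lag(counts, k), 0)
    return(correlation_curve(ks * bin_width, G,
                             meta = list(scheme = "direct",
                                         bin_width = bin_width,
                                         duration = duration,
                                         count_rate = sum(counts) / duration)))
  }

  m <- as.integer(channels_per_cascade)
  if (m < 2) fb_stop("channels_per_cascade must be >= 2", "validation_error")
  b <- bin_width
  lag_out <- numeric(0); G_out <- numeric(0)
  ks <- seq_len(2L * m)
  repeat {
    keep <- ks * b <= max_lag & ks < length(counts)
    if (!any(keep)) break
    for (k in ks[keep]) {
      lag_out <- c(lag_out, k * b)
      G_out <- c(G_out, corr_at_lag(counts, k))
    }
    # rebin by 2 (summing counts) and move to the coarser cascade
    n2 <- floor(length(counts) / 2) * 2
    counts <- counts[seq(1, n2, by = 2)] + counts[seq(2, n2, by = 2)]
    b <- 2 * b
    ks <- (m + 1L):(2L * m)
    if (length(counts) < 4L * m || (m + 1) * b > max_lag) break
  }
  ord <- order(lag_out)
  correlation_curve(lag_out[ord], G_out[ord],
                    meta = list(scheme = "multi_tau",
                                bin_width = bin_width,
                                channels_per_cascade = m,
                                duration = duration,
                                count_rate = sum(counts) / duration))
}

## symmetric-normalized correlation at integer lag k
corr_at_lag <- function(counts, k) {
  n <- length(counts)
  a <- counts[seq_len(n - k)]
  b <- counts[(k + 1):n]
  ma <- mean(a); mb <- mean(b)
  if (ma == 0 || mb == 0) return(0)
  mean(a * b) / (ma * mb) - 1
}

#' Fit the one-component 3D diffusion model to a correlation curve
#'
#' Weighted least squares of
#' `G(tau) = (1/N) (1 + tau/tD)^-1 (1 + tau/(kappa^2 tD))^-1/2 [+ offset]`
#' via Levenberg-Marquardt. Weights are taken from the curve's
#' `stderr` when present. The particle number is the reciprocal
#' amplitude, `PN = 1/G_fit(0)` (offset excluded). The structure
#' parameter is held fixed: it is an instrument calibration, not
#' identifiable from a single curve together with `N` and `tD`.
#'
#' @param curve a [correlation_curve()] with at least 10 lag points,
#'   ideally spanning two decades around `tD`.
#' @param kappa structure parameter (fixed).
#' @param fit_offset also fit an additive baseline offset.
#' @param start optional named list of starting values (`N`, `tD`).
#' @return an object of class `fcs_fit` with `PN`, `tD` (s), `kappa`,
#'   `offset`, `converged`; non-convergence is flagged, never silent.
#' @export
fit_diffusion_model <- function(curve, kappa = 5, fit_offset = FALSE,
                                start = NULL) {
  if (!inherits(curve, "correlation_curve"))
    fb_stop("curve must be a correlation_curve", "validation_error")
  if (length(curve$lags) < 10)
    fb_stop("need at least 10 lag points", "validation_error")
  if (log10(max(curve$lags) / min(curve$lags)) < 2)
    warning("lag range spans less than 2 decades; tD may be poorly constrained")
  tau <- curve$lags
  G <- curve$G
  g0 <- median(head(G, 3))
  if (!is.finite(g0) || g0 <= 0) g0 <- max(G)
  N0 <- start$N %||% (1 / g0)
  tD0 <- start$tD %||% {
    below <- which(G <= g0 / 2)
    if (length(below)) tau[below[1]] else median(tau)
  }
  w <- if (!is.null(curve$stderr) && all(curve$stderr > 0))
    1 / curve$stderr^2 else rep(1, length(tau))
  dat <- data.frame(tau = tau, G = G)
  fml <- if (fit_offset)
    G ~ 1 / (N * (1 + tau / tD) * sqrt(1 + tau / (kappa^2 * tD))) + off
  else
    G ~ 1 / (N * (1 + tau / tD) * sqrt(1 + tau / (kappa^2 * tD)))
  st <- if (fit_offset) list(N = N0, tD = tD0, off = 0)
        else list(N = N0, tD = tD0)
  lower <- if (fit_offset) c(1e-12, 1e-12, -Inf) else c(1e-12, 1e-12)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = dat, start = st, weights = w,
                      lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(PN = NA_real_, tD = NA_real_, kappa = kappa,
                          offset = NA_real_, converged = FALSE),
                     class = "fcs_fit"))
  }
  cf <- coef(fit)
  structure(list(PN = unname(cf["N"]), tD = unname(cf["tD"]),
                 kappa = kappa,
                 offset = if (fit_offset) unname(cf["off"]) else 0,
                 converged = isTRUE(fit$convInfo$isConv),
                 fit = fit),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("FCS fit: PN = %.3g, tD = %.4g ms (kappa = %g, offset %.3g)%s\n",
              x$PN, x$tD * 1e3, x$kappa, x$offset,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Maximum-likelihood fluorescence lifetime from TCSPC micro-times
#'
#' Tail fit of a mono-exponential decay plus uniform background to the
#' micro-times at or beyond `fit_window_start`. The likelihood uses the
#' exponential truncated to the fit window, so no instrument-response
#' deconvolution is needed provided the window starts past the
#' excitation peak; by default it starts 0.5 ns after the peak channel
#' of a coarse micro-time histogram.
#'
#' @param micro_times photon micro-times in ns, or a [photon_stream()].
#' @param pulse_period laser pulse period, ns.
#' @param fit_window_start left edge of the fit window, ns; `NULL` for
#'   the automatic peak + 0.5 ns choice.
#' @param min_photons minimum photons required inside the window.
#' @return an object of class `lifetime_fit` with `tau` (ns),
#'   `amplitude` (fitted signal fraction), `background` (uniform
#'   fraction), `se_tau` (observed-information standard error),
#'   `neg_log_likelihood`, `n_photons`, `window`.
#' @export
fit_lifetime <- function(micro_times, pulse_period,
                         fit_window_start = NULL, min_photons = 1000L) {
  if (inherits(micro_times, "photon_stream")) {
    pulse_period <- micro_times$meta$pulse_period_ns %||% pulse_period
    micro_times <- micro_times$micro_times
  }
  if (pulse_period <= 0)
    fb_stop("pulse_period must be positive", "validation_error")
  if (is.null(fit_window_start)) {
    h <- graphics::hist(micro_times, breaks = 256, plot = FALSE)
    fit_window_start <- h$mids[which.max(h$counts)] + 0.5
  }
  if (fit_window_start < 0 || fit_window_start >= pulse_period)
    fb_stop("fit_window_start must lie within the pulse period",
            "validation_error")
  s <- micro_times[micro_times >= fit_window_start] - fit_window_start
  L <- pulse_period - fit_window_start
  if (length(s) < min_photons)
    fb_stop(sprintf("only %d photons in fit window (need >= %d)",
                    length(s), min_photons), "insufficient_data_error")
  nll <- function(par) {
    tau <- exp(par[1]); a <- plogis(par[2])
    dens <- a * exp(-s / tau) / (tau * (1 - exp(-L / tau))) + (1 - a) / L
    -sum(log(dens))
  }
  tau0 <- min(mean(s), 0.8 * L)
  opt <- optim(c(log(tau0), qlogis(0.95)), nll, method = "BFGS",
               hessian = TRUE)
  tau_hat <- exp(opt$par[1])
  se_tau <- tryCatch({
    v <- solve(opt$hessian)[1, 1]          # var of log tau
    tau_hat * sqrt(max(v, 0))
  }, error = function(e) NA_real_)
  structure(list(tau = tau_hat, amplitude = plogis(opt$par[2]),
                 background = 1 - plogis(opt$par[2]),
                 se_tau = se_tau, neg_log_likelihood = opt$value,
                 n_photons = length(s),
                 window = c(fit_window_start, pulse_period)),
            class = "lifetime_fit")
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf(
    "Lifetime fit: tau = %.3f ns (SE %.3g), signal fraction %.3f, %d photons in [%.2f, %.2f] ns\n",
    x$tau, x$se_tau, x$amplitude, x$n_photons, x$window[1], x$window[2]))
  invisible(x)
}

#' Expected particle number at a given concentration
#'
#' `PN = c * N_A * V_eff` with the 3D Gaussian effective volume
#' `V_eff = pi^{3/2} w0^2 (kappa w0)`. This is the calibration value
#' against which a fitted particle number is judged: a freely diffusing
#' point-like species at concentration `c` should show this amplitude.
#'
#' @param conc molar concentration (>= 0).
#' @param w0 lateral beam radius, micrometers.
#' @param kappa structure parameter.
#' @return expected mean particle number in the effective volume.
#' @examples
#' expected_particle_number(1e-9, 0.35, 5)  # ~0.72 at 1 nM
#' @export
expected_particle_number <- function(conc, w0, kappa) {
  if (any(conc < 0) || w0 <= 0 || kappa <= 0)
    fb_stop("conc must be >= 0; w0, kappa positive", "validation_error")
  conc * AVOGADRO * pi^1.5 * w0^2 * (kappa * w0) * 1e-15
}

#' Classify DNA compaction state from a fitted particle number
#'
#' A relaxed plasmid coil carries several labelled segments per
#' molecule and overestimates the particle number; upon ligand-induced
#' folding into a point-like particle the fitted PN approaches the
#' concentration-expected value. The fitted PN is `"folded"` when
#' within `tol` of the expectation, `"relaxed"` when at least three
#' times the expectation, `"intermediate"` otherwise.
#'
#' @param fit an `fcs_fit` or a bare numeric particle number.
#' @param expected_pn expected PN from [expected_particle_number()].
#' @param tol folding tolerance (the reporting precision of PN, 0.1).
#' @return `"relaxed"`, `"folded"` or `"intermediate"`.
#' @export
classify_folding <- function(fit, expected_pn, tol = 0.1) {
  pn <- if (inherits(fit, "fcs_fit")) fit$PN else fit
  if (expected_pn <= 0)
    fb_stop("expected_pn must be positive", "validation_error")
  if (abs(pn - expected_pn) <= tol) "folded"
  else if (pn >= 3 * expected_pn) "relaxed"
  else "intermediate"
}
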