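#' Quenching titration series
#'
#' Container for a fluorescence quenching titration: quencher
#' concentrations, measured intensities and the control intensity `F0`
#' (no quencher). The concentration unit is carried explicitly because
#' fitted constants are returned in that unit (Stern-Volmer and binding
#' constants require molar input; membrane partition constants are
#' conventionally reported in micromolar).
#'
#' @param quencher_conc positive numeric vector of quencher concentrations.
#' @param F positive numeric vector of fluorescence intensities, same
#'   length as `quencher_conc`.
#' @param F0 positive scalar, control (unquenched) intensity.
#' @param unit concentration unit, `"M"` or `"uM"`.
#' @param replicate_id optional integer vector tagging replicates.
#' @param lip_conc optional positive scalar, liposome concentration in
#'   mg/mL (only meaningful for membrane partition titrations).
#' @return an object of class `titration_series`.
#' @export
titration_series <- function(quencher_conc, F, F0, unit = c("M", "uM"),
                             replicate_id = NULL, lip_conc = NULL) {
  unit <- match.arg(unit)
  if (length(quencher_conc) != length(F))
    fb_stop("quencher_conc and F must have equal length", "validation_error")
  if (any(!is.finite(quencher_conc)) || any(quencher_conc <= 0))
    fb_stop("quencher concentrations must be positive", "validation_error")
  if (any(!is.finite(F)) || any(F <= 0))
    fb_stop("fluorescence intensities must be positive", "validation_error")
  if (!is.finite(F0) || F0 <= 0)
    fb_stop("control intensity F0 must be positive", "validation_error")
  if (!is.null(replicate_id) && length(replicate_id) != length(F))
    fb_stop("replicate_id must match the series length", "validation_error")
  if (!is.null(lip_conc) && (!is.finite(lip_conc) || lip_conc <= 0))
    fb_stop("lip_conc must be positive", "validation_error")
  structure(
    list(quencher_conc = as.numeric(quencher_conc), F = as.numeric(F),
         F0 = as.numeric(F0), unit = unit,
         replicate_id = replicate_id, lip_conc = lip_conc),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat("Quenching titration:", length(x$F), "points,",
      sprintf("[Q] %g-%g %s, F0 = %g\n",
              min(x$quencher_conc), max(x$quencher_conc), x$unit, x$F0))
  invisible(x)
}

#' Polarized fluorescence readings
#'
#' A table of parallel/perpendicular intensity pairs with the instrument
#' G factor (the correction for the detection system's polarization
#' sensitivity).
#'
#' @param I_par,I_perp nonnegative numeric vectors of parallel and
#'   perpendicular emission intensities.
#' @param G positive scalar or vector, apparatus constant.
#' @return a `data.frame` of class `polarized_readings` with columns
#'   `I_par`, `I_perp`, `G`.
#' @export
polarized_readings <- function(I_par, I_perp, G = 1) {
  if (any(I_par < 0) || any(I_perp < 0))
    fb_stop("intensities must be nonnegative", "validation_error")
  if (any(G <= 0))
    fb_stop("G factor must be positive", "validation_error")
  d <- data.frame(I_par = I_par, I_perp = I_perp, G = G)
  if (any(d$I_par + 2 * d$G * d$I_perp <= 0))
    fb_stop("total intensity I_par + 2 G I_perp must be positive",
            "degenerate_input_error")
  class(d) <- c("polarized_readings", "data.frame")
  d
}

#' Photon arrival-time stream
#'
#' TCSPC photon records: each photon carries a macro-time (seconds since
#' the start of the measurement) and a micro-time (nanoseconds since the
#' previous laser pulse).
#'
#' @param macro_times nondecreasing numeric vector, seconds.
#' @param micro_times numeric vector, nanoseconds, same length; must lie
#'   in `[0, pulse_period_ns)` when a pulse period is given in `meta`.
#' @param meta named list of metadata; recognised entries are
#'   `duration` (s) and `pulse_period_ns`.
#' @return an object of class `photon_stream`.
#' @export
photon_stream <- function(macro_times, micro_times, meta = list()) {
  if (length(macro_times) != length(micro_times))
    fb_stop("macro and micro time vectors must have equal length",
            "validation_error")
  if (is.unsorted(macro_times))
    fb_stop("macro_times must be nondecreasing", "validation_error")
  pp <- meta$pulse_period_ns
  if (!is.null(pp) && length(micro_times) &&
      (any(micro_times < 0) || any(micro_times >= pp)))
    fb_stop("micro_times must lie in [0, pulse period)", "validation_error")
  structure(list(macro_times = as.numeric(macro_times),
                 micro_times = as.numeric(micro_times), meta = meta),
            class = "photon_stream")
}

#' @export
print.photon_stream <- function(x, ...) {
  dur <- x$meta$duration %||% if (length(x$macro_times)) max(x$macro_times) else 0
  cat(sprintf("Photon stream: %d photons over %.3g s (%.3g kcps)\n",
              length(x$macro_times), dur,
              if (dur > 0) length(x$macro_times) / dur / 1000 else 0))
  invisible(x)
}

#' Intensity autocorrelation curve
#'
#' @param lags strictly increasing positive numeric vector of lag times
#'   (seconds).
#' @param G numeric vector of correlation amplitudes
#'   `G(tau) = <dI(t) dI(t+tau)> / <I>^2`.
#' @param stderr optional numeric vector of per-lag standard errors,
#'   used as weights by [fit_diffusion_model()].
#' @param meta named list of provenance metadata.
#' @return an object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags, G, stderr = NULL, meta = list()) {
  if (length(lags) != length(G))
    fb_stop("lags and G must have equal length", "validation_error")
  if (any(lags <= 0) || is.unsorted(lags, strictly = TRUE))
    fb_stop("lags must be positive and strictly increasing",
            "validation_error")
  if (!is.null(stderr) && length(stderr) != length(G))
    fb_stop("stderr must match the curve length", "validation_error")
  structure(list(lags = as.numeric(lags), G = as.numeric(G),
                 stderr = stderr, meta = meta),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("Correlation curve: %d lags, %.3g s - %.3g s, G(min lag) = %.4g\n",
              length(x$lags), min(x$lags), max(x$lags), x$G[1]))
  invisible(x)
}

#' One-dimensional spectrum
#'
#' Ordered abscissa/signal pairs, used both for infrared absorbance
#' spectra (wavenumber in 1/cm) and fluorescence emission spectra
#' (wavelength in nm). [ftir_spectrum()] and [emission_spectrum()] are
#' thin wrappers fixing the axis unit.
#'
#' @param x strictly increasing numeric abscissa.
#' @param y numeric signal, same length.
#' @param xunit abscissa unit label (e.g. `"cm-1"`, `"nm"`).
#' @param label sample label.
#' @return an object of class `spectrum_xy`.
#' @export
spectrum_xy <- function(x, y, xunit = "cm-1", label = "") {
  if (length(x) != length(y))
    fb_stop("abscissa and signal must have equal length", "validation_error")
  if (is.unsorted(x, strictly = TRUE))
    fb_stop("abscissa must be strictly increasing", "validation_error")
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 xunit = xunit, label = label),
            class = "spectrum_xy")
}

#' @rdname spectrum_xy
#' @param wavenumber,absorbance infrared axes (1/cm, a.u.).
#' @export
ftir_spectrum <- function(wavenumber, absorbance, label = "")
  spectrum_xy(wavenumber, absorbance, xunit = "cm-1", label = label)

#' @rdname spectrum_xy
#' @param wavelength,intensity emission axes (nm, a.u.); intensities
#'   must be nonnegative.
#' @export
emission_spectrum <- function(wavelength, intensity, label = "") {
  if (any(intensity < 0))
    fb_stop("emission intensities must be nonnegative", "validation_error")
  spectrum_xy(wavelength, intensity, xunit = "nm", label = label)
}

#' @export
print.spectrum_xy <- function(x, ...) {
  cat(sprintf("Spectrum%s: %d points, %g-%g %s\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$x), min(x$x), max(x$x), x$xunit))
  invisible(x)
}

#' Wavenumber window for band-peak extraction
#'
#' @param name band label (e.g. `"nu_as_PO2"`).
#' @param lo,hi window bounds in 1/cm, `lo < hi`.
#' @param max_peaks maximum number of subband maxima to report
#'   (2 for bands that can split into hydration subbands).
#' @return an object of class `band_window`.
#' @export
band_window <- function(name, lo, hi, max_peaks = 1L) {
  if (!(lo < hi)) fb_stop("window requires lo < hi", "validation_error")
  if (max_peaks < 1) fb_stop("max_peaks must be >= 1", "validation_error")
  structure(list(name = name, lo = lo, hi = hi,
                 max_peaks = as.integer(max_peaks)),
            class = "band_window")
}

#' Grouped measurements for significance testing
#'
#' @param groups named list of numeric vectors, one per experimental
#'   group; every group needs at least two observations.
#' @param control_label name of the control group (defaults to the
#'   first).
#' @return an object of class `grouped_measurements`.
#' @export
grouped_measurements <- function(groups, control_label = names(groups)[1]) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    fb_stop("groups must be a fully named list", "validation_error")
  if (any(vapply(groups, length, 1L) < 2))
    fb_stop("every group needs at least 2 observations", "validation_error")
  if (!control_label %in% names(groups))
    fb_stop("control_label must name one of the groups", "validation_error")
  structure(list(groups = lapply(groups, as.numeric),
                 control_label = control_label),
            class = "grouped_measurements")
}
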