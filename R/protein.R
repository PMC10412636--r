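#' Inner-filter correction of observed fluorescence
#'
#' `F_corr = F_obs * 10^((A_ex + A_em)/2)`: compensates attenuation of
#' the excitation and emission beams by sample absorbance at the two
#' wavelengths. The corrected intensity is never smaller than the
#' observed one and is monotone increasing in each absorbance.
#'
#' @param F_obs observed intensity (positive; vectorized).
#' @param A_ex absorbance at the excitation wavelength (nonnegative).
#' @param A_em absorbance at the emission wavelength (nonnegative).
#' @return corrected intensity.
#' @examples
#' correct_inner_filter(50, 0.2, 0.1)  # 50 * 10^0.15
#' @export
correct_inner_filter <- function(F_obs, A_ex, A_em) {
  if (any(F_obs <= 0))
    fb_stop("F_obs must be positive", "validation_error")
  if (any(A_ex < 0) || any(A_em < 0))
    fb_stop("absorbances must be nonnegative", "validation_error")
  F_obs * 10^((A_ex + A_em) / 2)
}

## convert a titration's concentrations to molar for fits whose
## constants are conventionally quoted in 1/M
conc_molar <- function(series)
  switch(series$unit, M = series$quencher_conc,
         uM = series$quencher_conc * 1e-6)

#' Stern-Volmer quenching fit
#'
#' Ordinary least squares of `F0/F` against the molar quencher
#' concentration: `F0/F = 1 + K_SV [Q]`. The slope is the Stern-Volmer
#' constant; the bimolecular quenching constant follows as
#' `K_q = K_SV / tau0`. The intercept is fitted freely by default and
#' reported — its deviation from 1 is a diagnostic for curvature or
#' miscalibrated `F0`; `force_intercept = TRUE` pins it at 1.
#'
#' @param series a [titration_series()]; concentrations are converted
#'   to molar from the declared unit.
#' @param tau0 unquenched fluorophore lifetime in seconds (the
#'   conventional biopolymer value `5e-9` s by default).
#' @param force_intercept constrain the intercept to 1.
#' @return an object of class `stern_volmer_fit` with `K_SV` (1/M),
#'   `K_q` (1/(M s)), `tau0`, `intercept`, `se_K_SV`, `r_squared`.
#' @export
fit_stern_volmer <- function(series, tau0 = 5e-9, force_intercept = FALSE) {
  if (!inherits(series, "titration_series"))
    fb_stop("series must be a titration_series", "validation_error")
  if (tau0 <= 0) fb_stop("tau0 must be positive", "validation_error")
  q <- conc_molar(series)
  if (length(q) < 3)
    fb_stop("need at least 3 points", "insufficient_data_error")
  y <- series$F0 / series$F
  if (force_intercept) {
    fit <- lm(I(y - 1) ~ q + 0)
    sm <- suppressWarnings(summary(fit))
    slope <- unname(coef(fit)[1])
    intercept <- 1
    se <- sm$coefficients[1, 2]
  } else {
    fit <- lm(y ~ q)
    sm <- suppressWarnings(summary(fit))
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    se <- sm$coefficients[2, 2]
  }
  if (slope <= 0)
    warning("non-positive Stern-Volmer slope: no detectable quenching")
  structure(list(K_SV = slope, K_q = slope / tau0, tau0 = tau0,
                 intercept = intercept, se_K_SV = unname(se),
                 r_squared = sm$r.squared,
                 n_points_used = length(q)),
            class = "stern_volmer_fit")
}

#' @export
print.stern_volmer_fit <- function(x, ...) {
  cat(sprintf(
    "Stern-Volmer fit: K_SV = %.4g /M (SE %.3g), K_q = %.4g /M/s (tau0 = %g s), intercept %.4f, R^2 = %.4f\n",
    x$K_SV, x$se_K_SV, x$K_q, x$tau0, x$intercept, x$r_squared))
  invisible(x)
}

#' Double-logarithmic binding fit
#'
#' Ordinary least squares of `log10((F0 - F)/F)` against `log10([Q])`
#' (molar): the slope is the number of binding sites `n`, and the
#' binding constant is recovered from the intercept as
#' `K_b = 10^intercept`. Base-10 logarithms are used, the convention
#' for this plot. Points with `F >= F0` carry no binding signal and are
#' excluded and reported.
#'
#' @param series a [titration_series()]; concentrations are converted
#'   to molar from the declared unit.
#' @return an object of class `binding_fit` with `K_b` (effective 1/M),
#'   `n`, `se_log_Kb`, `se_n`, `r_squared`, `n_points_used`,
#'   `excluded_points`.
#' @export
fit_binding_double_log <- function(series) {
  if (!inherits(series, "titration_series"))
    fb_stop("series must be a titration_series", "validation_error")
  q <- conc_molar(series)
  usable <- series$F < series$F0
  excluded <- which(!usable)
  if (sum(usable) < 3)
    fb_stop("need at least 3 points with F < F0", "insufficient_data_error")
  y <- log10((series$F0 - series$F[usable]) / series$F[usable])
  x <- log10(q[usable])
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  structure(list(K_b = 10^unname(coef(fit)[1]), n = unname(coef(fit)[2]),
                 se_log_Kb = sm$coefficients[1, 2],
                 se_n = sm$coefficients[2, 2],
                 r_squared = sm$r.squared,
                 n_points_used = sum(usable),
                 excluded_points = excluded),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit: K_b = %.4g /M, n = %.3f (SE %.3g), R^2 = %.4f\n",
              x$K_b, x$n, x$se_n, x$r_squared))
  invisible(x)
}

#' Emission-spectrum summary: peak position and read-off intensity
#'
#' Locates the emission maximum by three-point parabolic interpolation
#' around the sampled maximum (sub-grid accuracy for smooth peaks) and
#' reads the intensity at a chosen wavelength by linear interpolation
#' (345 nm by default, the tryptophan emission maximum of serum
#' albumin).
#'
#' @param spectrum an [emission_spectrum()] (or any `spectrum_xy`).
#' @param read_at wavelength at which to read the intensity, nm; must
#'   lie within the sampled range.
#' @return list with `lambda_max` and `F_at_read`.
#' @export
emission_summary <- function(spectrum, read_at = 345) {
  if (!inherits(spectrum, "spectrum_xy"))
    fb_stop("spectrum must be a spectrum_xy object", "validation_error")
  wl <- spectrum$x; iy <- spectrum$y
  if (read_at < wl[1] || read_at > wl[length(wl)])
    fb_stop("read_at lies outside the sampled wavelength range",
            "validation_error")
  i <- which.max(iy)
  lambda_max <- if (i == 1 || i == length(iy)) wl[i]
                else parabolic_vertex(wl[(i - 1):(i + 1)],
                                      iy[(i - 1):(i + 1)])$x
  list(lambda_max = lambda_max,
       F_at_read = approx(wl, iy, xout = read_at)$y)
}

## vertex of the parabola through three points (exact 3-point quadratic)
parabolic_vertex <- function(x, y) {
  X <- cbind(1, x - x[2], (x - x[2])^2)
  ab <- solve(X, y)
  if (ab[3] == 0) return(list(x = x[2], y = y[2], curvature = 0))
  dx <- -ab[2] / (2 * ab[3])
  list(x = x[2] + dx, y = ab[1] + ab[2] * dx + ab[3] * dx^2,
       curvature = 2 * ab[3])
}
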