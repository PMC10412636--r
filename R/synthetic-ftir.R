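#' Infrared band specification
#'
#' One vibrational band for [gen_ftir_spectrum()]: position, full width
#' at half maximum, height and line shape (Gaussian, Lorentzian or a
#' pseudo-Voigt mixture with Lorentzian fraction `eta`).
#'
#' @param center band position, 1/cm.
#' @param fwhm full width at half maximum, 1/cm.
#' @param height peak height.
#' @param shape `"gaussian"`, `"lorentzian"` or `"pseudo_voigt"`.
#' @param eta pseudo-Voigt Lorentzian fraction in `[0, 1]`.
#' @return an object of class `band_spec`.
#' @export
band_spec <- function(center, fwhm, height = 1,
                      shape = c("gaussian", "lorentzian", "pseudo_voigt"),
                      eta = 0.5) {
  shape <- match.arg(shape)
  if (fwhm <= 0) fb_stop("fwhm must be positive", "validation_error")
  if (height <= 0) fb_stop("height must be positive", "validation_error")
  if (eta < 0 || eta > 1)
    fb_stop("eta must lie in [0, 1]", "validation_error")
  structure(list(center = center, fwhm = fwhm, height = height,
                 shape = shape, eta = eta),
            class = "band_spec")
}

band_profile <- function(band, x) {
  gauss <- exp(-4 * log(2) * (x - band$center)^2 / band$fwhm^2)
  lorentz <- 1 / (1 + (2 * (x - band$center) / band$fwhm)^2)
  band$height * switch(band$shape,
    gaussian = gauss,
    lorentzian = lorentz,
    pseudo_voigt = band$eta * lorentz + (1 - band$eta) * gauss)
}

#' Generate a synthetic ATR-FTIR spectrum
#'
#' Sums the requested band profiles over a regular wavenumber grid,
#' adds a polynomial baseline and optional additive Gaussian noise.
#'
#' @param bands nonempty list of [band_spec()] objects; every band
#'   center must lie inside the grid.
#' @param grid numeric `c(start, stop, step)` in 1/cm.
#' @param baseline polynomial coefficients in ascending powers of the
#'   wavenumber (default: flat zero baseline).
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param seed optional integer seed.
#' @param label sample label stored on the spectrum.
#' @return an [ftir_spectrum()].
#' @export
gen_ftir_spectrum <- function(bands, grid, baseline = 0, noise_sd = 0,
                              seed = NULL, label = "") {
  if (length(bands) == 0)
    fb_stop("at least one band is required", "validation_error")
  if (inherits(bands, "band_spec")) bands <- list(bands)
  if (!all(vapply(bands, inherits, TRUE, "band_spec")))
    fb_stop("bands must be band_spec objects", "validation_error")
  if (length(grid) != 3 || grid[3] <= 0 || grid[1] >= grid[2])
    fb_stop("grid must be c(start, stop, step) with step > 0",
            "validation_error")
  x <- seq(grid[1], grid[2], by = grid[3])
  centers <- vapply(bands, `[[`, 0, "center")
  if (any(centers < grid[1] | centers > grid[2]))
    fb_stop("all band centers must lie within the grid", "validation_error")
  y <- rowSums(vapply(bands, band_profile, numeric(length(x)), x = x))
  y <- y + drop(outer(x, seq_along(baseline) - 1, `^`) %*% baseline)
  if (noise_sd > 0)
    y <- y + with_seed(seed, rnorm(length(x), 0, noise_sd))
  ftir_spectrum(x, y, label = label)
}
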