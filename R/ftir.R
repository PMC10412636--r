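#' Default wavenumber windows for membrane lipid marker bands
#'
#' Windows bracketing the vibrational bands conventionally used as
#' markers of lipid headgroup hydration and acyl-chain order: the
#' choline antisymmetric C-N stretch, the symmetric and antisymmetric
#' phosphate stretches (allowed to split into two hydration subbands),
#' the ester carbonyl stretch and the two methylene stretches. All
#' bounds are overridable by constructing [band_window()] objects
#' directly.
#'
#' @return named list of [band_window()] objects.
#' @export
default_band_windows <- function() {
  w <- list(
    band_window("nu_as_NC",  960, 980, 1),
    band_window("nu_s_PO2",  1040, 1110, 2),
    band_window("nu_as_PO2", 1190, 1260, 2),
    band_window("nu_CO",     1700, 1780, 2),
    band_window("nu_s_CH2",  2840, 2870, 1),
    band_window("nu_as_CH2", 2905, 2940, 1)
  )
  setNames(w, vapply(w, `[[`, "", "name"))
}

## lower convex hull ("rubber band") baseline by Andrew's monotone chain
rubberband_baseline <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      # drop b if it lies above the chord a--i
      if ((x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a]) <= 0)
        hull <- hull[-length(hull)]
      else break
    }
    hull <- c(hull, i)
  }
  approx(x[hull], y[hull], xout = x)$y
}

#' Locate band maxima in a wavenumber window
#'
#' Finds local maxima of the (optionally baseline-corrected) signal
#' inside the window, filters them by topographic prominence, refines
#' each position by a three-point parabolic interpolation through the
#' samples around the maximum, and returns at most `max_peaks` peaks
#' ordered by height. Reporting more than one maximum supports bands
#' that split into subbands (e.g. the phosphate stretch separating into
#' less and more hydrated populations).
#'
#' Peak positions are invariant under linear baseline addition (removed
#' by the rubber-band correction) and under positive scaling of the
#' spectrum (which scales heights and prominences alike — use a
#' relative `min_prominence` of 0 to keep scale invariance strict).
#'
#' @param spectrum a [spectrum_xy()].
#' @param window a [band_window()] lying within the spectrum range and
#'   containing at least 5 samples.
#' @param min_prominence minimum prominence (same units as the signal)
#'   for a maximum to qualify.
#' @param baseline `"rubberband"` (lower convex hull of the windowed
#'   segment, subtracted before prominence testing) or `"none"`.
#' @return data frame with columns `position`, `height`, `fwhm`
#'   (parabolic full width at half maximum, a secondary diagnostic);
#'   zero rows when no maximum qualifies (not an error).
#' @export
find_band_peak <- function(spectrum, window, min_prominence = 0,
                           baseline = c("rubberband", "none")) {
  baseline <- match.arg(baseline)
  if (!inherits(spectrum, "spectrum_xy"))
    fb_stop("spectrum must be a spectrum_xy", "validation_error")
  if (!inherits(window, "band_window"))
    fb_stop("window must be a band_window", "validation_error")
  xr <- range(spectrum$x)
  if (window$lo < xr[1] || window$hi > xr[2])
    fb_stop("window lies outside the spectrum range", "validation_error")
  sel <- spectrum$x >= window$lo & spectrum$x <= window$hi
  if (sum(sel) < 5)
    fb_stop("need at least 5 samples inside the window",
            "validation_error")
  # baseline is estimated over the full spectrum, not the window: a
  # window-local hull chords across the band tails and tilts the peak
  ycorr <- if (baseline == "rubberband")
    spectrum$y - rubberband_baseline(spectrum$x, spectrum$y)
  else spectrum$y
  x <- spectrum$x[sel]
  y <- ycorr[sel]

  n <- length(y)
  cand <- which(diff(sign(diff(y))) == -2) + 1L
  if (!length(cand))
    return(data.frame(position = numeric(0), height = numeric(0),
                      fwhm = numeric(0)))
  prom <- vapply(cand, function(i) peak_prominence(y, i), 0)
  keep <- prom >= min_prominence & prom > 0
  cand <- cand[keep]
  if (!length(cand))
    return(data.frame(position = numeric(0), height = numeric(0),
                      fwhm = numeric(0)))
  refined <- lapply(cand, function(i) {
    v <- parabolic_vertex(x[(i - 1):(i + 1)], y[(i - 1):(i + 1)])
    # parabolic FWHM: width where the fitted parabola drops to half height
    fw <- if (v$curvature < 0 && v$y > 0)
      2 * sqrt(v$y / (-v$curvature)) else NA_real_
    c(position = v$x, height = v$y, fwhm = fw)
  })
  out <- as.data.frame(do.call(rbind, refined))
  out <- out[order(-out$height), , drop = FALSE]
  out <- head(out, window$max_peaks)
  rownames(out) <- NULL
  out
}

## topographic prominence of the local maximum at index i:
## height above the higher of the two key saddles (the minima toward
## the nearest strictly higher ground on each side, or the segment edge)
peak_prominence <- function(y, i) {
  n <- length(y)
  left <- if (i > 1) {
    higher <- which(y[seq_len(i - 1)] > y[i])
    lo <- if (length(higher)) (max(higher) + 1) else 1
    min(y[lo:(i - 1)])
  } else y[i]
  right <- if (i < n) {
    higher <- which(y[(i + 1):n] > y[i])
    hi <- if (length(higher)) (i + min(higher) - 1) else n
    min(y[(i + 1):hi])
  } else y[i]
  y[i] - max(left, right)
}

#' Band shift between a sample and a control spectrum
#'
#' Difference of the dominant band-peak positions (sample minus
#' control) inside one window. Negative values are shifts toward lower
#' wavenumbers — for the phosphate stretch, the signature of increased
#' headgroup hydration.
#'
#' @param sample,control [spectrum_xy()] objects covering the window.
#' @param window a [band_window()].
#' @param ... passed on to [find_band_peak()].
#' @return the shift in 1/cm.
#' @export
band_shift <- function(sample, control, window, ...) {
  ps <- find_band_peak(sample, window, ...)
  pc <- find_band_peak(control, window, ...)
  if (nrow(ps) == 0)
    fb_stop(sprintf("no band found in window '%s' of the sample spectrum",
                    window$name), "missing_band_error")
  if (nrow(pc) == 0)
    fb_stop(sprintf("no band found in window '%s' of the control spectrum",
                    window$name), "missing_band_error")
  ps$position[1] - pc$position[1]
}
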