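#' Fluorescence anisotropy
#'
#' `A = (Ipar - G Iperp) / (Ipar + 2 G Iperp)`, where `G` corrects the
#' detection system's differential sensitivity to the two polarization
#' components. The result is scale-invariant in the intensities and
#' bounded in `[-0.5, 1]` for nonnegative inputs.
#'
#' @param I_par parallel intensity (nonnegative), or a
#'   [polarized_readings()] data frame (in which case the other
#'   arguments are ignored).
#' @param I_perp perpendicular intensity (nonnegative).
#' @param G apparatus constant.
#' @return anisotropy value(s) in `[-0.5, 1]`.
#' @examples
#' compute_anisotropy(1, 1)        # isotropic: 0
#' compute_anisotropy(1, 0)        # fully polarized: 1
#' @export
compute_anisotropy <- function(I_par, I_perp = NULL, G = 1) {
  if (is.data.frame(I_par)) {
    d <- I_par
    I_par <- d$I_par; I_perp <- d$I_perp; G <- d$G
  }
  if (any(I_par < 0) || any(I_perp < 0) || any(G <= 0))
    fb_stop("intensities must be nonnegative and G positive",
            "validation_error")
  denom <- I_par + 2 * G * I_perp
  if (any(denom <= 0))
    fb_stop("zero total intensity: anisotropy undefined",
            "degenerate_input_error")
  (I_par - G * I_perp) / denom
}

#' Percent change relative to a control
#'
#' Expresses a measured value as a percentage decrease or increase with
#' respect to a positive control value, the convention used for
#' reporting probe intensity and anisotropy changes.
#'
#' @param value measured value(s).
#' @param control positive control value.
#' @param direction `"decrease"` (`100 (control - value)/control`) or
#'   `"increase"` (`100 (value - control)/control`).
#' @return percent change.
#' @export
percent_change <- function(value, control,
                           direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  if (!is.finite(control) || control <= 0)
    fb_stop("control must be positive", "validation_error")
  switch(direction,
         decrease = 100 * (control - value) / control,
         increase = 100 * (value - control) / control)
}

#' Membrane partition constant from a quenching titration
#'
#' Fits the double-reciprocal form of the hyperbolic partition law:
#' ordinary least squares of `y = 1/((F0/F) - 1)` against `x = 1/[Q]`
#' over points with `F < F0`, giving `K_d = slope / intercept` in the
#' concentration unit of the series. The liposome concentration scales
#' slope and intercept identically and cancels in `K_d`.
#'
#' Points with `F >= F0` are impossible under the model but can occur
#' under noise; they are excluded from the regression and reported in
#' `excluded_points`, never silently dropped. When the series carries
#' replicate tags the fit runs on per-concentration means by default;
#' `per_replicate = TRUE` additionally fits each replicate separately
#' and reports the spread of the per-replicate constants.
#'
#' Caveat: the reciprocal transform inflates the variance of
#' low-concentration points; the unweighted fit mirrors the
#' conventional graphical analysis.
#'
#' @param series a [titration_series()].
#' @param per_replicate also fit each replicate separately.
#' @return an object of class `partition_fit` with elements `K_d`,
#'   `slope`, `intercept`, `r_squared`, `se_K_d` (delta method),
#'   `n_points_used`, `excluded_points`, `unit` and, when requested,
#'   `K_d_replicates` / `K_d_sd`.
#' @export
fit_partition <- function(series, per_replicate = FALSE) {
  if (!inherits(series, "titration_series"))
    fb_stop("series must be a titration_series", "validation_error")
  conc <- series$quencher_conc
  Fv <- series$F
  if (!is.null(series$replicate_id)) {
    uc <- sort(unique(conc))
    Fv <- vapply(uc, function(c0) mean(Fv[conc == c0]), 0)
    conc <- uc
  }
  res <- partition_ols(conc, Fv, series$F0)
  out <- c(res, list(unit = series$unit))
  if (per_replicate && !is.null(series$replicate_id)) {
    kds <- vapply(unique(series$replicate_id), function(r) {
      sel <- series$replicate_id == r
      tryCatch(partition_ols(series$quencher_conc[sel], series$F[sel],
                             series$F0)$K_d,
               fluorobind_error = function(e) NA_real_)
    }, 0)
    out$K_d_replicates <- kds
    out$K_d_sd <- sd(kds, na.rm = TRUE)
  }
  structure(out, class = "partition_fit")
}

partition_ols <- function(conc, Fv, F0) {
  usable <- Fv < F0
  excluded <- which(!usable)
  if (sum(usable) < 3)
    fb_stop("need at least 3 points with F < F0", "insufficient_data_error")
  y <- 1 / ((F0 / Fv[usable]) - 1)
  x <- 1 / conc[usable]
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # noiseless input is legitimate here
  b <- coef(fit)
  intercept <- unname(b[1]); slope <- unname(b[2])
  if (intercept <= 0)
    fb_stop("non-physical fit: intercept of the double-reciprocal line is not positive",
            "non_physical_fit_error",
            data = list(slope = slope, intercept = intercept))
  V <- suppressWarnings(vcov(fit))
  # delta method for K_d = slope/intercept
  se <- sqrt(V[2, 2] / intercept^2 +
               slope^2 * V[1, 1] / intercept^4 -
               2 * slope * V[1, 2] / intercept^3)
  list(K_d = slope / intercept, slope = slope, intercept = intercept,
       r_squared = sm$r.squared, se_K_d = unname(se),
       n_points_used = sum(usable), excluded_points = excluded)
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("Partition fit: K_d = %.4g %s (SE %.3g), R^2 = %.4f, %d points used",
              x$K_d, x$unit, x$se_K_d, x$r_squared, x$n_points_used))
  if (length(x$excluded_points))
    cat(sprintf(", %d excluded (F >= F0)", length(x$excluded_points)))
  cat("\n")
  invisible(x)
}
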