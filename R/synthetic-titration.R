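#' Ground-truth parameters for a synthetic quenching titration
#'
#' Defines the generating model for [gen_quenching_titration()]. Exactly
#' the parameters that the chosen model requires must be supplied:
#'
#' * `stern_volmer`: `F0`, `K_SV` — intensities follow
#'   `F = F0 / (1 + K_SV * Q)`;
#' * `power_binding`: `F0`, `K_b`, `n` — `F = F0 / (1 + K_b * Q^n)`,
#'   the model whose double-log transform is linear with slope `n` and
#'   intercept `log10(K_b)`;
#' * `partition`: `F0`, `K_d`, `lip_conc` — quenching follows the
#'   hyperbolic partition law `(F0/F) - 1 = lip_conc * Q / (K_d + Q)`,
#'   the algebraic inverse of the double-reciprocal partition plot.
#'
#' `K_SV`, `K_b` and `K_d` are interpreted in the reciprocal of whatever
#' concentration unit the titration grid is laid out in.
#'
#' @param model one of `"stern_volmer"`, `"power_binding"`, `"partition"`.
#' @param F0 positive control intensity (arbitrary units).
#' @param K_SV Stern-Volmer constant (1/conc).
#' @param K_b binding constant (1/conc^n).
#' @param n number of binding sites (dimensionless).
#' @param K_d partition/dissociation constant (conc).
#' @param lip_conc liposome concentration (mg/mL); enters only as a
#'   dimensionless quenching scale and cancels in the fitted `K_d`.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   intensity noise (0 = noiseless).
#' @param seed optional integer seed.
#' @return an object of class `quench_ground_truth`.
#' @export
quench_ground_truth <- function(model = c("stern_volmer", "power_binding",
                                          "partition"),
                                F0, K_SV = NULL, K_b = NULL, n = NULL,
                                K_d = NULL, lip_conc = NULL,
                                noise_cv = 0, seed = NULL) {
  model <- match.arg(model)
  if (!is.finite(F0) || F0 <= 0)
    fb_stop("F0 must be positive", "configuration_error")
  if (!is.finite(noise_cv) || noise_cv < 0)
    fb_stop("noise_cv must be nonnegative", "configuration_error")
  required <- switch(model,
    stern_volmer  = list(K_SV = K_SV),
    power_binding = list(K_b = K_b, n = n),
    partition     = list(K_d = K_d, lip_conc = lip_conc))
  for (nm in names(required)) {
    v <- required[[nm]]
    if (is.null(v) || !is.finite(v) || v <= 0)
      fb_stop(sprintf("model '%s' requires positive parameter '%s'",
                      model, nm), "configuration_error")
  }
  extraneous <- setdiff(c("K_SV", "K_b", "n", "K_d", "lip_conc"),
                        names(required))
  supplied <- !vapply(mget(extraneous), is.null, TRUE)
  if (any(supplied))
    fb_stop(sprintf("parameter(s) %s are not part of model '%s'",
                    paste(extraneous[supplied], collapse = ", "), model),
            "configuration_error")
  structure(c(list(model = model, F0 = F0, noise_cv = noise_cv,
                   seed = seed), required),
            class = "quench_ground_truth")
}

#' Generate a synthetic quenching titration
#'
#' Evaluates the ground-truth quenching law on a concentration grid and
#' applies multiplicative lognormal noise with the requested coefficient
#' of variation (mean-one factors, so intensities stay positive and the
#' expected curve is unbiased). Seeded runs are bit-reproducible.
#'
#' @param truth a [quench_ground_truth()] object.
#' @param concentrations strictly positive, ascending quencher
#'   concentrations.
#' @param unit concentration unit tag stored on the series (`"M"` or
#'   `"uM"`); the ground-truth constants are interpreted in this unit.
#' @param replicates number of replicate readings per concentration.
#' @return a [titration_series()].
#' @examples
#' tr <- quench_ground_truth("stern_volmer", F0 = 100, K_SV = 1e4)
#' gen_quenching_titration(tr, c(1e-5, 1e-4))
#' @export
gen_quenching_titration <- function(truth, concentrations,
                                    unit = c("M", "uM"), replicates = 1L) {
  if (!inherits(truth, "quench_ground_truth"))
    fb_stop("truth must be a quench_ground_truth object",
            "configuration_error")
  unit <- match.arg(unit)
  q <- as.numeric(concentrations)
  if (any(!is.finite(q)) || any(q <= 0))
    fb_stop("concentrations must be strictly positive", "validation_error")
  if (is.unsorted(q, strictly = TRUE))
    fb_stop("concentrations must be sorted ascending", "validation_error")
  if (replicates < 1)
    fb_stop("replicates must be >= 1", "validation_error")

  F_clean <- switch(truth$model,
    stern_volmer  = truth$F0 / (1 + truth$K_SV * q),
    power_binding = truth$F0 / (1 + truth$K_b * q^truth$n),
    partition     = truth$F0 / (1 + truth$lip_conc * q / (truth$K_d + q)))

  conc <- rep(q, each = replicates)
  Fv <- rep(F_clean, each = replicates)
  rid <- if (replicates > 1L) rep(seq_len(replicates), times = length(q))
         else NULL
  Fv <- Fv * with_seed(truth$seed, lognormal_factor(length(Fv),
                                                    truth$noise_cv))
  titration_series(conc, Fv, F0 = truth$F0, unit = unit,
                   replicate_id = rid,
                   lip_conc = if (truth$model == "partition")
                     truth$lip_conc else NULL)
}

#' Generate polarized intensity readings at a set anisotropy
#'
#' Inverts the anisotropy definition `A = (Ipar - G Iperp)/(Ipar + 2 G
#' Iperp)`: noiseless readings satisfy it exactly with the requested
#' total intensity `Ipar + 2 G Iperp = total_I`. Multiplicative
#' lognormal noise (CV `noise_cv`) is applied independently per channel.
#'
#' @param true_A target anisotropy, in `[-0.5, 1]`.
#' @param total_I positive total intensity.
#' @param G apparatus constant.
#' @param noise_cv per-channel noise coefficient of variation.
#' @param n number of readings.
#' @param seed optional integer seed.
#' @return a [polarized_readings()] data frame.
#' @export
gen_polarized_readings <- function(true_A, total_I = 3, G = 1,
                                   noise_cv = 0, n = 1L, seed = NULL) {
  if (!is.finite(true_A) || true_A < -0.5 || true_A > 1)
    fb_stop("true_A must lie in [-0.5, 1]", "validation_error")
  if (total_I <= 0 || G <= 0)
    fb_stop("total_I and G must be positive", "validation_error")
  I_par <- total_I * (1 + 2 * true_A) / 3
  I_perp <- total_I * (1 - true_A) / (3 * G)
  with_seed(seed, {
    f1 <- lognormal_factor(n, noise_cv)
    f2 <- lognormal_factor(n, noise_cv)
    polarized_readings(I_par * f1, I_perp * f2, G = G)
  })
}
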