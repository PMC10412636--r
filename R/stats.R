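#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (equal-variance F test,
#' between/within sum-of-squares decomposition) on a
#' [grouped_measurements()] object. When every observation is
#' identical the test is vacuous and `F = 0`, `p = 1` is returned; a
#' zero within-group mean square with distinct means yields
#' `F = Inf`, `p = 0`.
#'
#' @param data a [grouped_measurements()] object.
#' @return list with `F_stat`, `p_value`, `df_between`, `df_within`,
#'   `ms_within`.
#' @export
one_way_anova <- function(data) {
  if (!inherits(data, "grouped_measurements"))
    fb_stop("data must be a grouped_measurements object", "validation_error")
  g <- data$groups
  k <- length(g)
  if (k < 2) fb_stop("need at least 2 groups", "validation_error")
  ni <- vapply(g, length, 1L)
  N <- sum(ni)
  df_b <- k - 1L
  df_w <- N - k
  means <- vapply(g, mean, 0)
  grand <- sum(ni * means) / N
  ss_b <- sum(ni * (means - grand)^2)
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  if (ss_b == 0 && ss_w == 0)
    return(list(F_stat = 0, p_value = 1, df_between = df_b,
                df_within = df_w, ms_within = 0))
  ms_b <- ss_b / df_b
  ms_w <- ss_w / df_w
  if (ms_w == 0)
    return(list(F_stat = Inf, p_value = 0, df_between = df_b,
                df_within = df_w, ms_within = 0))
  Fst <- ms_b / ms_w
  list(F_stat = Fst, p_value = pf(Fst, df_b, df_w, lower.tail = FALSE),
       df_between = df_b, df_within = df_w, ms_within = ms_w)
}

#' Duncan's multiple range test
#'
#' Stepwise post-hoc comparison of group means after a one-way ANOVA.
#' Means are sorted and a range of `p` adjacent means is declared
#' nonsignificant when it does not exceed the critical range
#' `R_p = q(1 - alpha_p, p, df) * sqrt(MSE / n_h)`, where the
#' studentized-range quantile uses Duncan's protection level
#' `alpha_p = 1 - (1 - alpha)^(p - 1)` (so for `p = 2` the decision
#' coincides with Fisher's LSD) and `n_h` is the harmonic mean group
#' size (the standard extension to mildly unbalanced designs).
#' Following the usual protection rule, any range contained in a
#' nonsignificant range is itself declared nonsignificant; the
#' resulting nonsignificance sets are intervals of the sorted means and
#' are rendered as a letter display. Groups not sharing a letter with
#' the control are flagged significantly different from it — the
#' "asterisks" of a control-versus-treatment figure.
#'
#' Quantiles of the studentized range are computed numerically
#' ([stats::qtukey()]); no tabulated critical values are used. Duncan's
#' test is known to be liberal: under a global null the per-comparison
#' flag rate runs somewhat above the nominal `alpha`.
#'
#' @param data a [grouped_measurements()] object.
#' @param alpha nominal significance level.
#' @return an object of class `significance_report`: `F_stat`,
#'   `p_value` (from the ANOVA), `letters` (named character),
#'   `vs_control_significant` (named logical), `alpha`, `means`, `n`,
#'   `ms_within`, `df_within`, `critical_ranges`, `control_label`.
#' @export
duncan_mrt <- function(data, alpha = 0.05) {
  if (!inherits(data, "grouped_measurements"))
    fb_stop("data must be a grouped_measurements object", "validation_error")
  g <- data$groups
  k <- length(g)
  if (k < 2) fb_stop("need at least 2 groups", "validation_error")
  aov_res <- one_way_anova(data)
  ni <- vapply(g, length, 1L)
  means <- vapply(g, mean, 0)
  mse <- aov_res$ms_within
  df_w <- aov_res$df_within
  n_h <- k / sum(1 / ni)

  ord <- order(means)                     # ascending
  ms <- means[ord]
  crit <- c(NA_real_,
            vapply(2:k, function(p) {
              alpha_p <- 1 - (1 - alpha)^(p - 1)
              qtukey(1 - alpha_p, p, df_w) * sqrt(mse / n_h)
            }, 0))

  # pairwise nonsignificance over sorted means; protection rule: a
  # range inside an already-nonsignificant range is never tested
  nonsig <- diag(TRUE, k)
  for (span in k:2) {
    for (i in seq_len(k - span + 1)) {
      j <- i + span - 1
      if (nonsig[i, j]) next
      if ((ms[j] - ms[i]) <= crit[span]) {
        nonsig[i:j, i:j] <- TRUE
      }
    }
  }

  # maximal nonsignificant intervals -> letters
  jmax <- vapply(seq_len(k), function(i) max(which(nonsig[i, ])), 1L)
  intervals <- unique(lapply(seq_len(k), function(i) c(i, jmax[i])))
  maximal <- Filter(function(ab) !any(vapply(intervals, function(cd)
    (cd[1] <= ab[1] && ab[2] <= cd[2] && !identical(cd, ab)), TRUE)),
    intervals)
  maximal <- maximal[order(vapply(maximal, `[`, 1L, 1))]
  lett_sorted <- rep("", k)
  for (i in seq_along(maximal)) {
    rng <- maximal[[i]][1]:maximal[[i]][2]
    lett_sorted[rng] <- paste0(lett_sorted[rng], letters[i])
  }
  lett <- setNames(character(k), names(g))
  lett[names(ms)] <- lett_sorted

  ctrl_pos <- which(names(ms) == data$control_label)
  vs_ctrl <- setNames(!nonsig[ctrl_pos, match(names(g), names(ms))],
                      names(g))

  structure(list(F_stat = aov_res$F_stat, p_value = aov_res$p_value,
                 letters = lett, vs_control_significant = vs_ctrl,
                 alpha = alpha, means = means, n = ni,
                 ms_within = mse, df_within = df_w,
                 critical_ranges = crit,
                 control_label = data$control_label),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.4g, p = %.3g; Duncan MRT at alpha = %g\n",
              x$F_stat, x$p_value, x$alpha))
  print(significance_table(x))
  invisible(x)
}

#' Annotated means table from a significance report
#'
#' Publication-style summary: one row per group with mean, SD, n, the
#' Duncan letter display and an asterisk for groups significantly
#' different from the control.
#'
#' @param report a `significance_report` from [duncan_mrt()].
#' @param data optional [grouped_measurements()] to recompute SDs from.
#' @return a data frame.
#' @export
significance_table <- function(report, data = NULL) {
  sds <- if (!is.null(data)) vapply(data$groups, sd, 0) else NA_real_
  data.frame(group = names(report$means),
             mean = unname(report$means),
             sd = if (!is.null(data)) unname(sds) else NA_real_,
             n = unname(report$n),
             letters = unname(report$letters),
             flag = ifelse(unname(report$vs_control_significant), "*", ""),
             row.names = NULL)
}

#' Format a "mean +/- SD" string
#'
#' @param mean,sd numeric vectors.
#' @param digits decimal places.
#' @return character vector like `"12.97 ± 2.92"`.
#' @export
format_mean_sd <- function(mean, sd, digits = 2)
  sprintf(paste0("%.", digits, "f ± %.", digits, "f"), mean, sd)
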