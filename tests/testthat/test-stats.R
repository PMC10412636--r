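test_that("one-way ANOVA matches the classical F test", {
  # identical groups: vacuous test
  g0 <- grouped_measurements(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  r0 <- one_way_anova(g0)
  expect_equal(r0$F_stat, 0)
  expect_equal(r0$p_value, 1)

  # two-group F equals the squared pooled t statistic
  with_seed(12, {
    x <- rnorm(6); y <- rnorm(6, 1)
  })
  g2 <- grouped_measurements(list(a = x, b = y))
  r2 <- one_way_anova(g2)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r2$F_stat, unname(tt$statistic)^2)
  expect_equal(r2$p_value, tt$p.value)

  # agreement with the stock equal-variance oneway test
  with_seed(13, g3 <- grouped_measurements(
    list(a = rnorm(8), b = rnorm(8, 0.5), c = rnorm(8, 1))))
  r3 <- one_way_anova(g3)
  ow <- oneway.test(values ~ grp, var.equal = TRUE,
                    data = data.frame(
                      values = unlist(g3$groups),
                      grp = rep(names(g3$groups), each = 8)))
  expect_equal(r3$F_stat, unname(ow$statistic))
  expect_equal(r3$p_value, unname(ow$p.value))
})

test_that("ANOVA holds its nominal type-I error", {
  with_seed(77, {
    rej <- vapply(1:10000, function(i) {
      g <- grouped_measurements(list(a = rnorm(10), b = rnorm(10),
                                     c = rnorm(10)))
      one_way_anova(g)$p_value < 0.05
    }, TRUE)
  })
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("Duncan's test flags separated groups and groups identical means", {
  # all groups identical: one shared letter, no flags
  g0 <- grouped_measurements(list(ctrl = c(1, 1, 2, 2), a = c(1, 2, 1, 2),
                                  b = c(2, 1, 2, 1)))
  r0 <- duncan_mrt(g0)
  expect_length(unique(r0$letters), 1)
  expect_false(any(r0$vs_control_significant))

  # a clearly separated third group is flagged against the control;
  # oracle: direct critical-range computation for the span-3 layout
  with_seed(42, g <- grouped_measurements(
    list(ctrl = rnorm(10, 0), a = rnorm(10, 0), b = rnorm(10, 5))))
  r <- duncan_mrt(g)
  expect_false(r$vs_control_significant[["a"]])
  expect_true(r$vs_control_significant[["b"]])
  expect_identical(r$letters[["ctrl"]], r$letters[["a"]])
  expect_false(r$letters[["b"]] %in% c(r$letters[["ctrl"]]))
  mse <- r$ms_within
  q2 <- qtukey(1 - 0.05, 2, r$df_within)
  expect_equal(r$critical_ranges[2], q2 * sqrt(mse / 10))

  # two-group decision coincides with Fisher's LSD at alpha
  with_seed(9, g2 <- grouped_measurements(list(a = rnorm(6), b = rnorm(6, 1.2))))
  r2 <- duncan_mrt(g2)
  lsd_p <- t.test(g2$groups$a, g2$groups$b, var.equal = TRUE)$p.value
  expect_identical(unname(r2$vs_control_significant["b"]), lsd_p < 0.05)
})

test_that("letter display exactly covers the nonsignificance structure", {
  with_seed(8, {
    for (i in 1:50) {
      k <- sample(3:6, 1)
      shift <- runif(k, 0, 3)
      g <- grouped_measurements(setNames(
        lapply(shift, function(m) rnorm(6, m)), paste0("g", 1:k)))
      r <- duncan_mrt(g)
      # two groups share a letter exactly when not flagged apart; check
      # via control flags under every choice of control
      for (ctrl in names(g$groups)) {
        g$control_label <- ctrl
        rc <- duncan_mrt(g)
        share <- vapply(names(g$groups), function(nm) {
          any(strsplit(rc$letters[[nm]], "")[[1]] %in%
                strsplit(rc$letters[[ctrl]], "")[[1]])
        }, TRUE)
        expect_identical(unname(!share), unname(rc$vs_control_significant))
      }
    }
  })
})

test_that("Duncan's test is shift-invariant and scale-equivariant", {
  with_seed(3, g <- grouped_measurements(
    list(ctrl = rnorm(8), a = rnorm(8, 1), b = rnorm(8, 2))))
  r <- duncan_mrt(g)
  g_shift <- grouped_measurements(lapply(g$groups, `+`, 100))
  g_scale <- grouped_measurements(lapply(g$groups, `*`, 7))
  expect_identical(duncan_mrt(g_shift)$letters, r$letters)
  expect_identical(duncan_mrt(g_scale)$letters, r$letters)
  expect_equal(duncan_mrt(g_scale)$critical_ranges[-1],
               7 * r$critical_ranges[-1])
})

test_that("the control flag runs near its nominal level under the null", {
  with_seed(55, {
    hits <- vapply(1:3000, function(i) {
      g <- grouped_measurements(list(ctrl = rnorm(8), a = rnorm(8),
                                     b = rnorm(8), c = rnorm(8)))
      mean(duncan_mrt(g)$vs_control_significant[-1])
    }, 0)
  })
  rate <- mean(hits)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.08)
})

test_that("report assembly renders publication-style tables", {
  with_seed(2, g <- grouped_measurements(
    list(ctrl = rnorm(5, 10), trt = rnorm(5, 14))))
  r <- duncan_mrt(g)
  tab <- significance_table(r, g)
  expect_identical(tab$group, c("ctrl", "trt"))
  expect_true(all(is.finite(tab$sd)))
  expect_identical(format_mean_sd(12.97, 2.92), "12.97 ± 2.92")
})
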