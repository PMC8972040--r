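make_trace <- function(time_min, conv, ref = NULL, red_conv = NULL,
                       red_non = NULL) {
  n <- length(time_min)
  frap_trace(time_min,
             green_converted = conv,
             green_reference = ref %||% rep(200, n),
             red_converted = red_conv %||% rep(100, n),
             red_nonconverted = red_non %||% rep(5, n))
}

test_that("green normalization follows the worked arithmetic", {
  # constant reference: later value (120 - 40) / (200 - 40) = 0.5
  tr <- make_trace(c(-10, 0, 10, 20, 30, 40),
                   conv = c(200, 40, 120, 120, 120, 120))
  ng <- normalize_green(tr)
  expect_equal(ng$value[1:3], c(1, 0, 0.5))

  # reference decayed 200 -> 160 at "later": corrected 120 * 200/160 = 150,
  # so (150 - 40) / (200 - 40) = 0.6875
  tr2 <- make_trace(c(-10, 0, 10, 20, 30, 40),
                    conv = c(200, 40, 120, 120, 120, 120),
                    ref = c(200, 200, 160, 160, 160, 160))
  expect_equal(normalize_green(tr2)$value[3], 0.6875)

  expect_error(normalize_green(make_trace(c(-10, 0, 10, 20, 30),
                                          conv = rep(50, 5))),
               "degenerate")
  bad <- make_trace(c(-10, 0, 10, 20, 30), conv = c(200, 40, 80, 90, 95))
  bad$green_reference[3] <- 0
  expect_error(normalize_green(bad), "index 3")
})

test_that("normalizing an already-normalized green trace is the identity", {
  t_min <- c(-10, seq(0, 600, by = 10))
  v <- c(1, 0.5524 * (1 - exp(-0.3 * seq(0, 600, by = 10) / 60)))
  v[2] <- 0   # post-conversion anchor
  v[1] <- 1   # pre-conversion anchor
  tr <- make_trace(t_min, conv = v, ref = rep(1, length(v)))
  expect_equal(normalize_green(tr)$value, v, tolerance = 1e-12)
})

test_that("red normalization removes a linear drift and rescales", {
  t_min <- c(-10, seq(0, 600, by = 10))
  t_h <- pmax(t_min, 0) / 60
  decay <- 100 * exp(-0.3 * t_h)
  drift <- -0.02 * pmax(t_min, 0)
  raw <- decay + drift + 20
  raw[1] <- 20   # pre-conversion red is baseline only
  tr <- frap_trace(t_min, green_converted = c(100, rep(50, 61)),
                   green_reference = rep(100, 62),
                   red_converted = raw, red_nonconverted = rep(20, 62))
  nr <- normalize_red(tr)
  cv <- attr(nr, "correction_value")
  # fitted slope = drift plus the residual exponential decay over the window
  expect_gt(cv, 0.02)
  expect_lt(cv, 0.06)
  # late-window slope of the corrected series shrinks by >= 90 %
  corrected <- raw + cv * t_min
  win <- t_min >= 500
  slope_before <- stats::coef(stats::lm(raw[win] ~ t_min[win]))[[2]]
  slope_after <- stats::coef(stats::lm(corrected[win] ~ t_min[win]))[[2]]
  expect_lt(abs(slope_after), 0.1 * abs(slope_before))
  expect_equal(nr$value[2], 1)   # post-conversion anchor
})

test_that("red normalization worked example and degenerate windows", {
  # drift-free series: correction ~ 0 and corrected == raw; with post value
  # 80 and baseline 5, a corrected later value of 42.5 normalizes to 0.5
  t_min <- c(-10, seq(0, 600, by = 10))
  raw <- c(5, seq(80, 42.5, length.out = 61))
  raw[32:62] <- 42.5   # flat late phase, no drift
  tr <- frap_trace(t_min, green_converted = c(100, rep(50, 61)),
                   green_reference = rep(100, 62),
                   red_converted = raw, red_nonconverted = rep(5, 62))
  nr <- normalize_red(tr)
  expect_equal(attr(nr, "correction_value"), 0, tolerance = 1e-9)
  expect_equal(nr$value[62], (42.5 - 5) / (80 - 5), tolerance = 1e-9)

  t_short <- c(-10, seq(0, 240, by = 20))
  short <- frap_trace(t_short,
                      green_converted = rep(10, length(t_short)),
                      green_reference = rep(10, length(t_short)),
                      red_converted = c(1, 80 - 0.1 * seq(0, 240, by = 20)),
                      red_nonconverted = rep(1, length(t_short)))
  expect_warning(normalize_red(short), "final 100 min")
  tiny <- frap_trace(c(-10, 0, 550, 600), green_converted = rep(1, 4),
                     green_reference = rep(1, 4),
                     red_converted = c(0, 10, 6, 5),
                     red_nonconverted = rep(0, 4))
  expect_error(normalize_red(tiny), "window error")
})

test_that("the exponential fit recovers generative parameters exactly", {
  t <- seq(0, 10, by = 1 / 6)
  norm <- tibble::tibble(time_h = t,
                         value = 0.6 * (1 - exp(-log(2) * t)) + 0)
  f <- fit_recovery(norm, channel = "green")
  expect_true(f$converged)
  expect_equal(f$Mf, 0.6, tolerance = 1e-6)
  expect_equal(f$t_half, 1, tolerance = 1e-6)
  expect_lt(f$residual_rms, 1e-8)
  # the fitted curve reaches half its amplitude exactly at t_half
  expect_equal(f$Mf * (1 - exp(-f$b * f$t_half)), f$Mf / 2,
               tolerance = 1e-9)
})

test_that("a constant series is flagged as unidentifiable", {
  norm <- tibble::tibble(time_h = seq(0, 10, by = 0.5),
                         value = rep(0.3, 21))
  f <- fit_recovery(norm, channel = "green")
  expect_false(f$converged)
  expect_lt(f$Mf, 0.05)
  expect_true(is.na(f$t_half))
})

test_that("the red transform equals the green path on the mirrored series", {
  t <- seq(0, 10, by = 0.25)
  y <- 1 - 0.67 * (1 - exp(-0.5 * t))   # decreasing red-style series
  red_fit <- fit_recovery(tibble::tibble(time_h = t, value = y),
                          channel = "red")
  green_fit <- fit_recovery(tibble::tibble(time_h = t, value = 1 - y),
                            channel = "green")
  expect_equal(red_fit$Mf, green_fit$Mf, tolerance = 1e-9)
  expect_equal(red_fit$b, green_fit$b, tolerance = 1e-9)
})

test_that("tidy and glance expose the fit in broom form", {
  t <- seq(0, 10, by = 0.5)
  f <- fit_recovery(tibble::tibble(time_h = t,
                                   value = 0.5 * (1 - exp(-t)) + 0.01))
  td <- tidy(f)
  expect_identical(td$term, c("Mf", "b", "c"))
  gl <- glance(f)
  expect_identical(names(gl),
                   c("Mf", "b", "c", "t_half", "residual_rms",
                     "converged", "n"))
  expect_equal(gl$t_half, log(2) / gl$b)
})

test_that("group comparison behaves like Student's t-test", {
  t <- seq(0, 10, by = 0.5)
  mk_fit <- function(mf) {
    fit_recovery(tibble::tibble(time_h = t,
                                value = mf * (1 - exp(-0.6 * t))))
  }
  a <- lapply(c(0.5, 0.6, 0.7), mk_fit)
  expect_error(compare_mf(a, a[1]), "insufficient data")

  same <- compare_mf(a, a)
  expect_equal(same$statistic, c(0, 0))
  expect_equal(same$p_value, c(1, 1))

  b <- lapply(c(0.5, 0.6, 0.7) + 0.4, mk_fit)
  shifted <- compare_mf(a, b)
  mf_row <- shifted[shifted$metric == "Mf", ]
  expect_gt(abs(mf_row$statistic), 4)
  expect_lt(mf_row$p_value, 0.05)

  # permutation oracle on the Mf values (exhaustive over 20 splits)
  vals <- c(0.5, 0.6, 0.7, 0.9, 1.0, 1.1)
  obs <- abs(mean(vals[1:3]) - mean(vals[4:6]))
  perms <- utils::combn(6, 3)
  null_d <- apply(perms, 2, function(ix) {
    abs(mean(vals[ix]) - mean(vals[-ix]))
  })
  p_perm <- mean(null_d >= obs - 1e-12)
  expect_lt(p_perm, 0.11)   # 2/20: only the observed split and its mirror
  expect_lt(mf_row$p_value, p_perm + 0.05)
})
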