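test_that("line_scan recovers a rendered profile through an image", {
  scan <- render_line_scan(sites_green(), geom_default, render_quiet)
  img <- scan_to_image(scan, height = 7)
  n <- ncol(img$green)
  poly <- data.frame(x = c(0, n - 1), y = c(3, 3))
  got <- line_scan(img, poly, width_px = 1,
                   pixel_size = attr(scan, "pixel_size"))
  expect_equal(got$green, scan$green, tolerance = 1e-12)
  expect_equal(got$red, scan$red, tolerance = 1e-12)

  # a laterally uniform stripe gives the same answer at any width
  got5 <- line_scan(img, poly, width_px = 5,
                    pixel_size = attr(scan, "pixel_size"))
  expect_equal(got5$green, got$green, tolerance = 1e-12)

  expect_error(line_scan(img, data.frame(x = c(-10, 5), y = c(3, 3))),
               "outside")
})

test_that("diagonal line scans match a brute-force bilinear oracle", {
  set.seed(5)
  img <- list(green = matrix(runif(30 * 40), 30, 40),
              red = matrix(runif(30 * 40), 30, 40))
  poly <- data.frame(x = c(2, 35), y = c(3, 25))
  got <- line_scan(img, poly, width_px = 1, pixel_size = 1)

  bilin <- function(mat, x, y) {
    x0 <- floor(x); y0 <- floor(y); fx <- x - x0; fy <- y - y0
    mat[y0 + 1, x0 + 1] * (1 - fx) * (1 - fy) +
      mat[y0 + 1, x0 + 2] * fx * (1 - fy) +
      mat[y0 + 2, x0 + 1] * (1 - fx) * fy +
      mat[y0 + 2, x0 + 2] * fx * fy
  }
  L <- sqrt(33^2 + 22^2)
  s <- unique(c(seq(0, L, by = 1), L))
  ox <- 2 + 33 / L * s
  oy <- 3 + 22 / L * s
  oracle <- vapply(seq_along(s), function(i) {
    bilin(img$green, ox[i], oy[i])
  }, numeric(1))
  expect_equal(got$green, oracle, tolerance = 1e-6)
})

test_that("polynomial fitting is exact on polynomial data", {
  x <- seq(0, 2, by = 0.05)
  y <- 2 - 0.5 * x + 3 * x^2 - x^4
  scan <- tibble::new_tibble(
    list(position_um = x, green = y, red = rep(1, length(x))),
    class = "line_scan")
  fit <- fit_polynomial(scan, degree = 4)
  expect_lt(max(abs(predict_channel(fit, x, "green") - y)), 1e-9)

  fit0 <- fit_polynomial(scan, degree = 0)
  expect_equal(predict_channel(fit0, x, "red"), rep(1, length(x)))

  expect_error(fit_polynomial(scan[1:4, ], degree = 4), "samples")
})

test_that("turning points land on the analytic minima of a cosine profile", {
  x <- seq(0, 40, by = 0.5)
  y <- 1 - cos(2 * pi * x / 20)
  scan <- tibble::new_tibble(
    list(position_um = x, green = y, red = rep(0.1, length(x))),
    class = "line_scan")
  fit <- fit_polynomial(scan, degree = 10)
  tp <- find_turning_points(fit)
  # the two analytic peaks sit at 10 and 30; whichever is principal, its
  # nearest flanking minima are 10 px away (the 0/20/40 cosine minima)
  expect_true(min(abs(tp$peak - c(10, 30))) < 0.3)
  expect_equal(tp$left, tp$peak - 10, tolerance = 0.6)
  expect_equal(tp$right, tp$peak + 10, tolerance = 0.6)

  ramp <- tibble::new_tibble(
    list(position_um = x, green = x, red = x), class = "line_scan")
  expect_error(find_turning_points(fit_polynomial(ramp, degree = 4)),
               "boundary error")
})

test_that("Z-band spacing on a wide scan matches the sarcomere length", {
  scan <- render_line_scan(sites_green(), geom_default, render_quiet,
                           window_half_um = 2.25)
  fit <- fit_polynomial(scan, degree = 10)
  tp <- find_turning_points(fit)
  spacing <- tp$right - tp$left
  expect_lt(abs(spacing - 2.0) / 2.0, 0.02)
  # the M-line estimate (turning-point midpoint) sits on the true center
  expect_lt(abs((tp$right + tp$left) / 2), 0.05)
})

test_that("extraction normalizes, zeroes endpoints and maps pixels affinely", {
  # quadratic through (10, 0.2), (30, 1.3), (50, 0.4): the baseline through
  # the turning-point values is 0.3 at the midpoint, so the peak value 1.3
  # maps to 1.0 before max-normalization
  px <- seq(0, 60, by = 1)
  lagr <- function(x) {
    0.2 * ((x - 30) * (x - 50)) / ((10 - 30) * (10 - 50)) +
      1.3 * ((x - 10) * (x - 50)) / ((30 - 10) * (30 - 50)) +
      0.4 * ((x - 10) * (x - 30)) / ((50 - 10) * (50 - 30))
  }
  scan <- tibble::new_tibble(
    list(position_um = px, green = lagr(px), red = lagr(px) * 0.5),
    class = "line_scan")
  fit <- fit_polynomial(scan, degree = 2)
  w <- extract_sarcomere(fit, list(left = 10, right = 50))

  expect_equal(max(w$green), 1)
  expect_equal(w$green[1], 0)
  expect_equal(w$green[201], 0)
  expect_equal(w$x_norm[1], -1)
  expect_equal(w$x_norm[101], 0)
  # pixel 40 maps to x = +0.5
  q <- function(x) lagr(x) - (0.2 + (0.4 - 0.2) * (x - 10) / 40)
  xg <- seq(10, 50, length.out = 201)
  expect_equal(w$green[w$x_norm == 0.5], q(40) / max(q(xg)),
               tolerance = 1e-6)
})

test_that("symmetric profiles give exactly symmetric waveforms", {
  w <- scan_to_waveform(render_line_scan(sites_green(), geom_default,
                                         render_quiet))
  expect_equal(w$green, rev(w$green), tolerance = 1e-12)
  expect_equal(w$red, rev(w$red), tolerance = 1e-12)
})

test_that("the filament tips sit near +/- 0.8 in normalized coordinates", {
  w <- scan_to_waveform(render_line_scan(sites_green(), geom_default,
                                         render_quiet))
  # half-max crossing of the green edge tracks the filament tip
  right_half <- w$x_norm[w$x_norm > 0][which.min(
    abs(w$green[w$x_norm > 0] - 0.5))]
  expect_gt(right_half, 0.6)
  expect_lt(right_half, 0.9)
  # the tip coordinate itself is filament_length / sarcomere_length = 0.8
  expect_equal(geom_default$x_tip, 0.8)
})

test_that("an empty channel is flagged instead of normalized", {
  scan <- render_line_scan(sites_green(), geom_default, render_quiet)
  w <- scan_to_waveform(scan)
  expect_identical(attr(w, "empty_channels"), "red")
  expect_equal(attr(w, "red_scale"), 0)
  expect_true(all(w$red == 0))
})

test_that("waveform differences behave and stay bounded", {
  w <- make_waveform(red_fun = function(x) pmax(1 - (x / 0.85)^2, 0))
  d <- subtract_waveforms(w)
  expect_true(all(abs(d$diff) < 1e-12))

  # green 1 - x^2 against a red Gaussian pair at +/- 0.7 (sd 0.15):
  # d(0.7) = 1 - 0.51 = 0.49
  w2 <- make_waveform(
    red_fun = function(x) {
      exp(-(x - 0.7)^2 / (2 * 0.15^2)) + exp(-(x + 0.7)^2 / (2 * 0.15^2))
    },
    green_fun = function(x) 1 - x^2
  )
  d2 <- subtract_waveforms(w2)
  expect_equal(d2$diff[d2$x_norm == 0.7], 0.49, tolerance = 0.015)

  dm <- build_difference_map(list(w, w2))
  expect_s3_class(dm, "difference_map")
  expect_true(all(dm$diff >= -1 & dm$diff <= 1))
})

test_that("mirroring a scan mirrors waveform and difference profile", {
  geom <- geom_default
  sel <- geom$x > 0.55
  scan <- render_line_scan(sites_with_red(sel), geom, render_quiet)
  mirrored <- scan
  mirrored$green <- rev(scan$green)
  mirrored$red <- rev(scan$red)
  w1 <- scan_to_waveform(scan)
  w2 <- scan_to_waveform(mirrored)
  expect_equal(w1$green, rev(w2$green), tolerance = 1e-8)
  expect_equal(w1$red, rev(w2$red), tolerance = 1e-8)
  d1 <- subtract_waveforms(w1)
  d2 <- subtract_waveforms(w2)
  expect_equal(d1$diff, rev(d2$diff), tolerance = 1e-8)
})

test_that("difference maps average across sarcomeres per time point", {
  wa <- make_waveform(gauss(0.5), id = 1L, time_min = 10)
  wb <- make_waveform(gauss(-0.5), id = 2L, time_min = 10)
  dm <- build_difference_map(list(wa, wb))
  expect_equal(nrow(dm), 201L)
  # averaged red is the mean of the two Gaussians before subtraction
  mean_red <- (wa$red + wb$red) / 2
  expect_equal(dm$diff, mean_red - wa$green, tolerance = 1e-12)
})
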