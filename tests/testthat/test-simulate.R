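test_that("simulation is deterministic and conserves occupancy", {
  kin <- exchange_kinetics("pool", A1 = 0.6, k1 = 1, A2 = 0.2, k2 = 0.05)
  a <- simulate_exchange(geom_default, kin, label_protocol("photoconversion"),
                         duration = 5, seed = 42)
  b <- simulate_exchange(geom_default, kin, label_protocol("photoconversion"),
                         duration = 5, seed = 42)
  expect_identical(a$labels, b$labels)
  expect_identical(a$sites, b$sites)
  # replaced fraction is non-decreasing; every label is green or red
  expect_true(all(diff(a$replaced$replaced) >= 0))
  expect_true(all(a$labels %in% c("green", "red")))
  expect_equal(nrow(a$labels), 300L)
})

test_that("zero rates freeze the filament", {
  kin <- exchange_kinetics("pool", A1 = 0, k1 = 1, A2 = 0, k2 = 1)
  sim <- simulate_exchange(geom_default, kin, label_protocol("pulse_chase"),
                           duration = 10, seed = 1)
  expect_true(all(sim$replaced$replaced == 0))
  expect_true(all(sim$labels == "green"))
})

test_that("uniform-rate replacement tracks 1 - exp(-kt) within 3 binomial SE", {
  for (k in c(0.1, 0.231, 1)) {
    kin <- exchange_kinetics("pool", A1 = 1, k1 = k, A2 = 0, k2 = 0)
    for (tt in c(0.5, 3, 8)) {
      sim <- simulate_exchange(geom_default, kin,
                               label_protocol("photoconversion"),
                               duration = tt, times = tt,
                               seed = round(1000 * k + tt))
      expected <- 1 - exp(-k * tt)
      se <- sqrt(expected * (1 - expected) / 300)
      expect_lt(abs(sim$replaced$replaced - expected), 3 * se + 1e-12)
    }
  }
})

test_that("tip-biased replacement matches a per-site Monte-Carlo oracle", {
  # k_tip / k_center = 4, short time so p ~ k t
  kin <- exchange_kinetics("profile", k_center = 0.25, k_tip = 1,
                           exponent = 2)
  geom <- geom_default
  tt <- 0.05
  u <- abs(geom$x) / geom$x_tip
  outer <- which(u > 2 / 3)
  inner <- which(u < 1 / 3)

  # brute-force oracle: 1e5 exponential waiting-time draws per region,
  # sites sampled uniformly within the region
  set.seed(99)
  draw_region <- function(idx) {
    rates <- 0.25 + 0.75 * u[idx]^2
    pick <- sample(rates, 1e5, replace = TRUE)
    mean(stats::rexp(1e5, pick) <= tt)
  }
  oracle_ratio <- draw_region(outer) / draw_region(inner)

  reps <- vapply(1:300, function(s) {
    sim <- simulate_exchange(geom, kin, label_protocol("photoconversion"),
                             duration = tt, times = tt, seed = 7000 + s)
    c(mean(sim$sites$first_event[outer] <= tt),
      mean(sim$sites$first_event[inner] <= tt))
  }, numeric(2))
  sim_ratio <- mean(reps[1, ]) / mean(reps[2, ])

  mean_rate_ratio <- mean(0.25 + 0.75 * u[outer]^2) /
    mean(0.25 + 0.75 * u[inner]^2)
  expect_equal(sim_ratio, oracle_ratio, tolerance = 0.1)
  expect_equal(sim_ratio, mean_rate_ratio, tolerance = 0.1)
})

test_that("invalid simulation configurations are rejected", {
  kin <- exchange_kinetics("pool", A1 = 0.5, k1 = 1, A2 = 0, k2 = 0)
  expect_error(simulate_exchange(geom_default, kin,
                                 label_protocol("photoconversion"),
                                 duration = -1), "duration")
})

test_that("noiseless FRAP traces reproduce the analytic recovery exactly", {
  kin <- exchange_kinetics("pool", A1 = 0.6, k1 = 0.4, A2 = 0, k2 = 0)
  tr <- simulate_frap_trace(kin, render_config(noise_sd = 0),
                            times = seq(0, 10, by = 0.5))
  ng <- normalize_green(tr)
  post <- ng$time_h >= 0
  expect_equal(ng$value[post], 0.6 * (1 - exp(-0.4 * ng$time_h[post])),
               tolerance = 1e-12)
  expect_error(simulate_frap_trace(kin, times = numeric(0)), "non-empty")
})

test_that("photobleaching cancels out of the normalized green trace", {
  kin <- exchange_kinetics("pool", A1 = 0.6, k1 = 0.4, A2 = 0, k2 = 0)
  tr <- simulate_frap_trace(kin, render_config(noise_sd = 0,
                                               bleach_rate_green = 0.1),
                            times = seq(0, 10, by = 0.5))
  # reference ROI visibly decays
  expect_lt(tr$green_reference[nrow(tr)], tr$green_reference[1] * 0.5)
  ng <- normalize_green(tr)
  truth <- attr(tr, "truth")
  expect_equal(ng$value[ng$time_h >= 0], truth$replaced, tolerance = 1e-12)
})

test_that("rendered line scans mirror when the label field mirrors", {
  geom <- geom_default
  sel <- geom$x > 0.6 | (geom$x > -0.3 & geom$x < -0.1)
  s1 <- sites_with_red(sel)
  s2 <- sites_with_red(rev(sel))   # positions are symmetric, so this mirrors
  a <- render_line_scan(s1, geom, render_quiet)
  b <- render_line_scan(s2, geom, render_quiet)
  expect_equal(a$green, rev(b$green), tolerance = 1e-12)
  expect_equal(a$red, rev(b$red), tolerance = 1e-12)
})

test_that("a label-free channel renders as pure background", {
  scan <- render_line_scan(sites_green(), geom_default, render_quiet)
  expect_equal(scan$red, rep(render_quiet$background, nrow(scan)))
  expect_gt(max(scan$green), 10 * render_quiet$background)
  expect_error(render_line_scan(sites_green(), geom_default,
                                render_config(pixel_size = 2.5)),
               "pixel_size")
})

test_that("pulse-chase populations carry coherent ground truth", {
  pop <- generate_pulse_chase_population(chase_time_min = 0,
                                         n_sarcomeres = 6, n_myotubes = 2,
                                         seed = 3)
  expect_true(all(pop$truth$truth_category == "no_incorporation"))
  expect_true(all(pop$truth$n_red == 0))

  # uniform kinetics and a long chase relabel most sites everywhere: red
  # shape tracks green shape and the random pattern is the modal category
  unif <- exchange_kinetics("pool", A1 = 1, k1 = 1, A2 = 0, k2 = 0)
  pop2 <- generate_pulse_chase_population(chase_time_min = 72,
                                          n_sarcomeres = 40, n_myotubes = 2,
                                          kinetics = unif, seed = 4)
  tab <- table(pop2$truth$truth_category)
  expect_identical(names(which.max(tab)), "random_fashion")
  expect_gt(tab[["random_fashion"]] / sum(tab), 0.25)
  expect_error(generate_pulse_chase_population(10, n_sarcomeres = 0),
               "n_sarcomeres")
})
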