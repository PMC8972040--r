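#' Simulate stochastic per-myosin exchange on a thick filament
#'
#' Each myosin site exchanges as an independent Poisson process at its own
#' rate (see [site_rates()]); at each event the occupant is replaced by a
#' myosin carrying the pool label dictated by the protocol at that time.
#' Because sites are non-interacting, independent exponential waiting times
#' are an exact sampling scheme (equivalent to a Gillespie simulation of the
#' full system). The myosin molecule is the exchange unit: occupancy is
#' conserved at every event (one occupant out, one in).
#'
#' @param geometry A [filament_geometry()].
#' @param kinetics An [exchange_kinetics()].
#' @param protocol A [label_protocol()]. The simulation clock starts at the
#'   protocol's labeling event (`t = 0`).
#' @param duration Simulated time span after the event, hours (> 0).
#' @param times Sample times (hours in `[0, duration]`) at which label
#'   states are recorded; defaults to 61 evenly spaced times.
#' @param seed Integer seed; identical seed and configuration give an
#'   identical result.
#' @return An object of class `exchange_sim`: a list with `sites` (a tibble
#'   of site position, rate, first event time and event count), `times`,
#'   `labels` (site-by-time character matrix of `"green"`/`"red"`),
#'   `replaced` (tibble of time and ground-truth replaced fraction),
#'   `protocol`, `geometry`, `kinetics` and `seed`.
#' @examples
#' kin <- exchange_kinetics(mode = "pool", A1 = 1, k1 = log(2) / 3, A2 = 0, k2 = 0)
#' sim <- simulate_exchange(filament_geometry(), kin,
#'                          label_protocol("photoconversion"),
#'                          duration = 3, seed = 1)
#' tail(sim$replaced, 1)   # close to 0.5 at one half-life
#' @export
simulate_exchange <- function(geometry, kinetics, protocol,
                              duration, times = NULL, seed = NULL) {
  stopifnot(inherits(geometry, "filament_geometry"),
            inherits(kinetics, "exchange_kinetics"),
            inherits(protocol, "label_protocol"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be > 0", call. = FALSE)
  }
  rates <- site_rates(kinetics, geometry)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("invalid configuration: rates must be finite and >= 0", call. = FALSE)
  }
  if (length(rates) == 0L) {
    stop("invalid configuration: zero myosin sites", call. = FALSE)
  }
  if (is.null(times)) times <- seq(0, duration, length.out = 61)
  if (!is.null(seed)) set.seed(seed)

  n <- length(rates)
  first_event <- rep(Inf, n)
  n_events <- integer(n)
  for (i in seq_len(n)) {
    if (rates[i] <= 0) next
    t_acc <- stats::rexp(1, rates[i])
    if (t_acc <= duration) first_event[i] <- t_acc
    k <- 0L
    while (t_acc <= duration) {
      k <- k + 1L
      t_acc <- t_acc + stats::rexp(1, rates[i])
    }
    n_events[i] <- k
  }

  old_label <- if (protocol$mode == "photoconversion") "red" else "green"
  new_label <- if (protocol$mode == "photoconversion") "green" else "red"
  labels <- vapply(times, function(tt) {
    ifelse(first_event <= tt, new_label, old_label)
  }, character(n))
  labels <- matrix(labels, nrow = n)
  replaced <- vapply(times, function(tt) mean(first_event <= tt), numeric(1))

  structure(
    list(sites = tibble::tibble(site = seq_len(n), x = geometry$x,
                                rate = rates, first_event = first_event,
                                n_events = n_events),
         times = times,
         labels = labels,
         replaced = tibble::tibble(time_h = times, replaced = replaced),
         protocol = protocol, geometry = geometry, kinetics = kinetics,
         seed = seed),
    class = "exchange_sim"
  )
}

#' Label state of a simulated filament at one time
#'
#' @param sim An `exchange_sim` from [simulate_exchange()].
#' @param t Time in hours (must not exceed the simulated duration).
#' @return A tibble with columns `x` (normalized site position) and `label`
#'   (`"green"` or `"red"`).
#' @export
exchange_state <- function(sim, t) {
  stopifnot(inherits(sim, "exchange_sim"))
  if (t < 0 || t > max(sim$times)) {
    stop("t outside simulated range", call. = FALSE)
  }
  old_label <- if (sim$protocol$mode == "photoconversion") "red" else "green"
  new_label <- if (sim$protocol$mode == "photoconversion") "green" else "red"
  tibble::tibble(
    x = sim$sites$x,
    label = ifelse(sim$sites$first_event <= t, new_label, old_label)
  )
}

#' Render a synthetic two-channel FRAP trace
#'
#' Produces the raw ROI intensity time series a photoconversion experiment
#' yields, from the analytic (mean-field) replaced-fraction curve of the
#' kinetics. The converted-ROI green signal recovers with the replaced
#' fraction, the converted-ROI red signal decays with its complement, a
#' reference (non-converted) ROI carries the green photobleaching decay, and
#' a non-photoconverted-area red baseline carries the red zero level. A
#' pre-conversion sample is prepended at -10 min. Artifacts per the
#' [render_config()]: multiplicative green bleaching, additive linear red
#' drift on the converted ROI, additive Gaussian noise on all ROIs.
#'
#' @param kinetics An [exchange_kinetics()].
#' @param render A [render_config()].
#' @param times Post-conversion sample times, hours; default a 10-min grid
#'   to 10 h.
#' @param seed Integer seed for the noise stream.
#' @param geometry Filament geometry (only used by profile-mode kinetics).
#' @return A [frap_trace()] with the ground-truth replaced-fraction curve in
#'   attribute `"truth"`.
#' @export
simulate_frap_trace <- function(kinetics, render = render_config(),
                                times = seq(0, 10, by = 1 / 6),
                                seed = NULL,
                                geometry = filament_geometry()) {
  stopifnot(inherits(kinetics, "exchange_kinetics"),
            inherits(render, "render_config"))
  if (length(times) == 0L) stop("times must be non-empty", call. = FALSE)
  times <- sort(times)
  if (times[1] < 0) stop("post-conversion times must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  f <- replaced_fraction(kinetics, times, geometry)
  sc <- render$intensity_scale
  bg <- render$background
  t_pre <- -1 / 6
  all_t <- c(t_pre, times)
  bleach <- exp(-render$bleach_rate_green * (all_t - t_pre))

  green_conv <- sc * (bg + c(1, f)) * bleach
  green_ref <- sc * (bg + 1) * bleach
  red_conv <- sc * (bg + c(0, 1 - f))
  drift <- render$red_linear_drift * pmax(all_t, 0) * 60   # per-minute drift
  red_conv <- red_conv - sc * drift
  red_nonconv <- rep(sc * bg, length(all_t))

  if (render$noise_sd > 0) {
    nz <- function(v) v + stats::rnorm(length(v), sd = render$noise_sd * sc)
    green_conv <- nz(green_conv); green_ref <- nz(green_ref)
    red_conv <- nz(red_conv); red_nonconv <- nz(red_nonconv)
  }

  tr <- frap_trace(time_min = all_t * 60,
                   green_converted = pmax(green_conv, 0),
                   green_reference = pmax(green_ref, 1e-9),
                   red_converted = pmax(red_conv, 0),
                   red_nonconverted = pmax(red_nonconv, 0),
                   pre_index = 1L, post_index = 2L)
  attr(tr, "truth") <- tibble::tibble(time_h = times, replaced = f)
  attr(tr, "seed") <- seed
  tr
}

# deterministic sub-stream seed derivation (stays below 2^31 - 1)
derive_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * i) %% 2147483629)
}

#' Render a two-channel line scan from labeled myosin positions
#'
#' Every myosin contributes a unit-amplitude Gaussian of width `psf_sigma`
#' at its axial position (micrometres from the M-line) in the channel of its
#' current label. The profile is sampled at `pixel_size` over a window
#' centred on the sarcomere; by default the filament is tiled at
#' `+/- sarcomere_length` so the scan sees the shoulders of the neighboring
#' sarcomeres and the inter-sarcomere intensity minima that mark the
#' Z-bands. Background (a fraction of the peak total signal) and Gaussian
#' noise are added per the [render_config()].
#'
#' @param sites A data frame with columns `x` (normalized position, M-line
#'   0) and `label` (`"green"`, `"red"`, anything else is dark), e.g. from
#'   [exchange_state()].
#' @param geometry A [filament_geometry()].
#' @param render A [render_config()].
#' @param window_half_um Scan half-width, micrometres; defaults to 1.25x the
#'   half-sarcomere so both Z-band minima are inside the scan.
#' @param tile Include neighboring sarcomere copies of the filament.
#' @param seed Optional integer seed for the noise stream.
#' @param time_min Optional acquisition time recorded on the scan.
#' @return A tibble of class `line_scan` with columns `position_um`,
#'   `green`, `red`; ground-truth label positions kept in attribute
#'   `"sites"`.
#' @export
render_line_scan <- function(sites, geometry = filament_geometry(),
                             render = render_config(),
                             window_half_um = NULL, tile = TRUE,
                             seed = NULL, time_min = NA_real_) {
  stopifnot(is.data.frame(sites), all(c("x", "label") %in% names(sites)),
            inherits(geometry, "filament_geometry"),
            inherits(render, "render_config"))
  if (render$pixel_size >= geometry$sarcomere_length) {
    stop("pixel_size must be smaller than the sarcomere length", call. = FALSE)
  }
  if (render$psf_sigma >= geometry$filament_length / 2) {
    stop("psf_sigma must be smaller than half the filament length",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  half_s <- geometry$sarcomere_length / 2
  if (is.null(window_half_um)) window_half_um <- 1.25 * half_s
  pos_um <- sites$x * half_s
  offsets <- if (tile) c(-1, 0, 1) * geometry$sarcomere_length else 0
  grid <- seq(-window_half_um, window_half_um, by = render$pixel_size)

  channel_profile <- function(label) {
    p <- rep(0, length(grid))
    centers <- as.vector(outer(pos_um[sites$label == label], offsets, "+"))
    for (cc in centers) {
      p <- p + exp(-(grid - cc)^2 / (2 * render$psf_sigma^2))
    }
    p
  }
  green <- channel_profile("green")
  red <- channel_profile("red")
  # per-channel auto-gain, as acquisition software scales each detector
  # channel independently; a channel with no label stays at background
  if (max(green) > 0) green <- green / max(green)
  if (max(red) > 0) red <- red / max(red)
  green <- green + render$background
  red <- red + render$background
  if (render$noise_sd > 0) {
    green <- green + stats::rnorm(length(grid), sd = render$noise_sd)
    red <- red + stats::rnorm(length(grid), sd = render$noise_sd)
  }
  out <- tibble::new_tibble(
    list(position_um = grid, green = green, red = red),
    class = "line_scan"
  )
  attr(out, "pixel_size") <- render$pixel_size
  attr(out, "time_min") <- time_min
  attr(out, "sites") <- sites
  out
}

#' Generate a ground-truthed pulse-chase sarcomere population
#'
#' Simulates `n_sarcomeres` independent thick filaments under a pulse-chase
#' protocol (pre-existing myosin green, myosin inserted during the chase
#' red), renders each as a two-channel line scan, and extracts its
#' normalized waveform. For every sarcomere a ground-truth incorporation
#' category is assigned by running the identical waveform pipeline and
#' classification rules on a noise-free rendering of the same label state,
#' so truth and measurement differ only by acquisition noise.
#'
#' @param chase_time_min Chase duration, minutes.
#' @param n_sarcomeres Number of sarcomeres (>= 1).
#' @param n_myotubes Number of pseudo-myotubes the sarcomeres are divided
#'   into (for between-myotube summary statistics).
#' @param kinetics Exchange kinetics; default the `"tip_biased"`
#'   preset.
#' @param geometry,render,rules Geometry, rendering and classification-rule
#'   configuration.
#' @param degree Polynomial degree for waveform extraction.
#' @param seed Master integer seed; per-sarcomere sub-streams are derived
#'   deterministically.
#' @return An object of class `pulse_chase_population`: a list with
#'   `waveforms` (list of `sarcomere_waveform`), `truth` (tibble of
#'   sarcomere id, myotube, chase time, truth category and true red site
#'   positions), and the configuration. Sarcomeres whose scan could not be
#'   segmented are dropped and counted in `n_failed`.
#' @export
generate_pulse_chase_population <- function(chase_time_min,
                                            n_sarcomeres = 150,
                                            n_myotubes = 6,
                                            kinetics = kinetics_preset("tip_biased"),
                                            geometry = filament_geometry(),
                                            render = render_config(),
                                            rules = classification_rules(),
                                            degree = 6,
                                            seed = NULL) {
  if (n_sarcomeres < 1) stop("n_sarcomeres must be >= 1", call. = FALSE)
  rates <- site_rates(kinetics, geometry)
  t_h <- chase_time_min / 60
  p_red <- 1 - exp(-rates * t_h)
  render0 <- render
  render0$noise_sd <- 0

  waveforms <- vector("list", n_sarcomeres)
  rows <- vector("list", n_sarcomeres)
  myotube <- rep(seq_len(n_myotubes), length.out = n_sarcomeres)
  n_failed <- 0L
  for (i in seq_len(n_sarcomeres)) {
    s <- derive_seed(seed, i)
    if (!is.null(s)) set.seed(s)
    red <- stats::runif(length(rates)) < p_red
    sites <- tibble::tibble(x = geometry$x,
                            label = ifelse(red, "red", "green"))
    res <- tryCatch({
      scan0 <- render_line_scan(sites, geometry, render0,
                                time_min = chase_time_min)
      w0 <- scan_to_waveform(scan0, degree = degree)
      truth_cat <- classify_pattern(w0, rules)$category
      scan <- render_line_scan(sites, geometry, render,
                               time_min = chase_time_min)
      w <- scan_to_waveform(scan, degree = degree)
      attr(w, "sarcomere_id") <- i
      attr(w, "myotube") <- myotube[i]
      list(w = w, truth = truth_cat)
    }, error = function(e) NULL)
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    waveforms[[i]] <- res$w
    rows[[i]] <- tibble::tibble(
      sarcomere_id = i, myotube = myotube[i], time_min = chase_time_min,
      truth_category = res$truth, n_red = sum(red),
      red_x = list(geometry$x[red])
    )
  }
  keep <- !vapply(waveforms, is.null, logical(1))
  structure(
    list(waveforms = waveforms[keep],
         truth = dplyr::bind_rows(rows[keep]),
         chase_time_min = chase_time_min,
         n_failed = n_failed,
         kinetics = kinetics, geometry = geometry, render = render,
         rules = rules, degree = degree, seed = seed),
    class = "pulse_chase_population"
  )
}

#' Simulate a photoconversion time series of sarcomere waveforms
#'
#' Runs [simulate_exchange()] for several myofibrils under the
#' photoconversion protocol (all incorporated myosin turns red at t = 0,
#' incoming myosin is green), renders line scans at the requested times and
#' extracts normalized waveforms, giving the input for red-green difference
#' mapping over time.
#'
#' @param kinetics Exchange kinetics (a tip-biased profile makes the
#'   spatial release bias visible in the difference map).
#' @param times_min Acquisition times, minutes after photoconversion.
#' @param n_fibrils Number of independent myofibrils.
#' @param geometry,render Geometry and rendering configuration.
#' @param degree Polynomial degree for waveform extraction.
#' @param seed Master seed.
#' @return A long tibble with columns `fibril`, `time_min`, `x_norm`,
#'   `green`, `red` (one normalized waveform per fibril and time).
#' @export
generate_photoconversion_series <- function(kinetics = kinetics_preset("tip_biased_photoconv"),
                                            times_min = seq(0, 200, by = 10),
                                            n_fibrils = 7,
                                            geometry = filament_geometry(),
                                            render = render_config(),
                                            degree = 6,
                                            seed = NULL) {
  out <- vector("list", n_fibrils * length(times_min))
  k <- 0L
  for (fb in seq_len(n_fibrils)) {
    sim <- simulate_exchange(geometry, kinetics,
                             label_protocol("photoconversion"),
                             duration = max(times_min) / 60 + 1e-9,
                             times = pmax(times_min, 1e-12) / 60,
                             seed = derive_seed(seed, fb))
    for (j in seq_along(times_min)) {
      st <- exchange_state(sim, pmax(times_min[j], 1e-12) / 60)
      scan <- render_line_scan(st, geometry, render,
                               seed = derive_seed(seed, 1000L * fb + j),
                               time_min = times_min[j])
      # total (green + red) fluorescence traces the sarcomere structure at
      # all times; the green channel alone is empty right after conversion
      w <- tryCatch(scan_to_waveform(scan, degree = degree,
                                     tp_channel = "total"),
                    error = function(e) NULL)
      if (is.null(w)) next
      k <- k + 1L
      out[[k]] <- tibble::tibble(fibril = fb, time_min = times_min[j],
                                 x_norm = w$x_norm,
                                 green = w$green, red = w$red)
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}
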