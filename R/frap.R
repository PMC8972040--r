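#' Construct a raw two-channel photoconversion trace
#'
#' Container for the four ROI intensity time series a photoconversion
#' experiment produces: the converted-area green and red signals, a
#' non-converted reference region for the green photobleaching correction,
#' and a non-photoconverted-area red baseline defining the red zero level.
#'
#' @param time_min Sample times, minutes (strictly increasing; the
#'   pre-conversion sample has a negative time by convention).
#' @param green_converted,green_reference,red_converted,red_nonconverted
#'   Raw mean ROI intensities (arbitrary units, `>= 0`).
#' @param pre_index,post_index Row indices of the last pre-conversion and
#'   first post-conversion samples.
#' @return A tibble of class `frap_trace`.
#' @export
frap_trace <- function(time_min, green_converted, green_reference,
                       red_converted, red_nonconverted,
                       pre_index = 1L, post_index = 2L) {
  n <- length(time_min)
  stopifnot(length(green_converted) == n, length(green_reference) == n,
            length(red_converted) == n, length(red_nonconverted) == n)
  if (any(diff(time_min) <= 0)) {
    stop("time_min must be strictly increasing", call. = FALSE)
  }
  if (pre_index >= post_index) {
    stop("pre_index must precede post_index", call. = FALSE)
  }
  if (any(c(green_converted, green_reference,
            red_converted, red_nonconverted) < 0)) {
    stop("raw intensities must be >= 0", call. = FALSE)
  }
  out <- tibble::new_tibble(
    list(time_min = as.numeric(time_min),
         green_converted = as.numeric(green_converted),
         green_reference = as.numeric(green_reference),
         red_converted = as.numeric(red_converted),
         red_nonconverted = as.numeric(red_nonconverted)),
    class = "frap_trace"
  )
  attr(out, "pre_index") <- as.integer(pre_index)
  attr(out, "post_index") <- as.integer(post_index)
  out
}

new_normalized_trace <- function(time_min, value, channel, post_index,
                                 correction_value = NA_real_) {
  out <- tibble::new_tibble(
    list(time_min = time_min, time_h = time_min / 60, value = value),
    class = "normalized_trace"
  )
  attr(out, "channel") <- channel
  attr(out, "post_index") <- post_index
  attr(out, "correction_value") <- correction_value
  out
}

#' Normalize the green (recovery) channel of a photoconversion trace
#'
#' The converted-area green signal is first corrected for photobleaching by
#' multiplying with `reference(pre) / reference(t)`, then rescaled affinely
#' so the pre-conversion value maps to 1 and the first post-conversion
#' value maps to 0. On this scale the trace is the fraction of the
#' pre-conversion green signal recovered, i.e. the fraction of myosin
#' replaced by unconverted molecules.
#'
#' @param trace A [frap_trace()].
#' @return A tibble of class `normalized_trace` (columns `time_min`,
#'   `time_h`, `value`) with attribute `channel = "green"`.
#' @export
normalize_green <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  pre <- attr(trace, "pre_index"); post <- attr(trace, "post_index")
  ref <- trace$green_reference
  if (any(ref <= 0)) {
    stop(sprintf("division error: reference intensity <= 0 at time index %d",
                 which(ref <= 0)[1]), call. = FALSE)
  }
  v <- trace$green_converted * ref[pre] / ref
  den <- v[pre] - v[post]
  if (abs(den) < 1e-12) {
    stop("degenerate trace: zero dynamic range between pre and post",
         call. = FALSE)
  }
  new_normalized_trace(trace$time_min, (v - v[post]) / den, "green", post)
}

#' Normalize the red (decay) channel of a photoconversion trace
#'
#' A slow linear instrument drift is removed using the late-trace slope: the
#' least-squares slope of the raw converted-ROI red intensity over the
#' 500-600 min window is taken, its negative stored as the correction value
#' (intensity per minute), and `correction_value * time` is added to the raw
#' signal, which cancels the drift while leaving the exchange decay (which
#' has essentially flattened by 500 min) untouched. The corrected series is
#' then rescaled so the first post-conversion value maps to 1 and the
#' non-photoconverted-area red level (taken per time point) maps to 0.
#'
#' If the trace ends before 600 min the final 100 min are used instead,
#' with a warning; the window must contain at least 3 samples.
#'
#' Because the drift is an instrument artifact of the imaging session, a
#' correction value shared by all traces of a session can be supplied
#' instead of the per-trace estimate; see [estimate_red_correction()] for
#' the pooled session-level estimator, which is considerably less noisy
#' than a single trace's window slope.
#'
#' @param trace A [frap_trace()].
#' @param correction_value Optional externally estimated correction value
#'   (intensity per minute); when `NULL` it is estimated from this trace's
#'   own window.
#' @return A tibble of class `normalized_trace` with attributes
#'   `channel = "red"` and `correction_value`.
#' @export
normalize_red <- function(trace, correction_value = NULL) {
  stopifnot(inherits(trace, "frap_trace"))
  post <- attr(trace, "post_index")
  t_min <- trace$time_min
  if (is.null(correction_value)) {
    win <- red_correction_window(trace)
    slope <- stats::coef(stats::lm(trace$red_converted[win] ~ t_min[win]))[[2]]
    correction_value <- -slope
  }
  corrected <- trace$red_converted + correction_value * t_min
  zero <- trace$red_nonconverted
  den <- corrected[post] - zero[post]
  if (abs(den) < 1e-12) {
    stop("degenerate trace: zero red dynamic range at post-conversion",
         call. = FALSE)
  }
  new_normalized_trace(t_min, (corrected - zero) / den, "red", post,
                       correction_value = correction_value)
}

red_correction_window <- function(trace) {
  t_min <- trace$time_min
  t_end <- max(t_min)
  if (t_end >= 600) {
    win <- t_min >= 500 & t_min <= 600
  } else {
    warning(sprintf(paste0("trace ends at %.0f min (< 600); using the final ",
                           "100 min for the drift correction window"), t_end))
    win <- t_min >= t_end - 100
  }
  win <- win & seq_along(t_min) >= attr(trace, "post_index")
  if (sum(win) < 3L) {
    stop("window error: fewer than 3 samples in the drift-correction window",
         call. = FALSE)
  }
  win
}

#' Session-level red drift correction value
#'
#' Pools the late-window samples of several traces from the same imaging
#' session and fits a common slope with per-trace intercepts. The linear
#' red drift is an instrument artifact shared by all ROIs of a session, so
#' the pooled slope estimate shrinks the correction noise by roughly the
#' square root of the number of traces relative to a per-trace estimate.
#'
#' @param traces A list of [frap_trace()] objects.
#' @return The correction value (intensity per minute) to pass to
#'   [normalize_red()].
#' @export
estimate_red_correction <- function(traces) {
  stopifnot(length(traces) >= 1)
  dat <- dplyr::bind_rows(lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    win <- red_correction_window(tr)
    data.frame(t = tr$time_min[win], red = tr$red_converted[win], id = i)
  }))
  fit <- if (length(traces) > 1L) {
    stats::lm(red ~ t + factor(id), data = dat)
  } else {
    stats::lm(red ~ t, data = dat)
  }
  -stats::coef(fit)[["t"]]
}

#' Fit the single-exponential recovery model
#'
#' Fits `FI(t) = Mf * (1 - exp(-b * t)) + c` to the post-conversion samples
#' of a normalized trace by bounded Levenberg-Marquardt nonlinear least
#' squares. The red channel is decreasing, so its change magnitude
#' `1 - value` is fitted, putting both channels on the same increasing form;
#' the mobile fraction `Mf` is therefore always the maximum change of
#' normalized fluorescence, and `t_half = log(2) / b` is the time for the
#' change to reach half of `Mf`.
#'
#' Starting values are taken from the data (`Mf`: observed range; `b`:
#' log(2) over the half-range crossing time; `c`: first value), with up to 5
#' restarts from perturbed rate constants. Bounds: `Mf` in `[0, 1.5]`, `b`
#' in `(0, 100]` per hour, `c` in `[-0.5, 0.5]`. A fit whose rate lands on a
#' bound (e.g. a constant series, for which `b` is unidentifiable) is
#' flagged as not converged.
#'
#' @param norm A `normalized_trace` from [normalize_green()] /
#'   [normalize_red()], or any data frame with columns `time_h` and `value`
#'   (all rows with `time_h >= 0` are fitted).
#' @param channel Channel orientation; defaults to the trace's own.
#' @return An object of class `frap_fit` with elements `Mf`, `b`, `c`,
#'   `t_half` (hours), `residual_rms`, `converged`, `channel`, `n` and the
#'   fitted data. See [tidy.frap_fit()] and [glance.frap_fit()].
#' @export
fit_recovery <- function(norm, channel = NULL) {
  stopifnot(is.data.frame(norm), all(c("time_h", "value") %in% names(norm)))
  if (is.null(channel)) channel <- attr(norm, "channel") %||% "green"
  keep <- norm$time_h >= 0
  t <- norm$time_h[keep]
  y <- norm$value[keep]
  if (length(t) < 5L) stop("need >= 5 post-event samples", call. = FALSE)
  if (channel == "red") y <- 1 - y
  t <- t - t[1]      # time origin at the first post-conversion frame

  if (stats::sd(y) < 1e-12) {
    # constant series: no amplitude, rate unidentifiable
    out <- list(Mf = 0, b = NA_real_, c = mean(y), t_half = NA_real_,
                residual_rms = 0, converged = FALSE, channel = channel,
                n = length(t), data = data.frame(t = t, y = y), fit = NULL,
                diagnostics = "constant series: rate unidentifiable")
    class(out) <- "frap_fit"
    return(out)
  }

  Mf0 <- max(y) - min(y)
  c0 <- y[1]
  cross <- which(y >= c0 + Mf0 / 2)
  b0 <- if (length(cross) > 0 && t[cross[1]] > 0) log(2) / t[cross[1]] else 1
  b0 <- min(max(b0, 1e-3), 50)

  dat <- data.frame(t = t, y = y)
  do_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ Mf * (1 - exp(-b * t)) + c, data = dat, start = start,
        lower = c(Mf = 0, b = 1e-6, c = -0.5),
        upper = c(Mf = 1.5, b = 100, c = 0.5),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  starts <- lapply(c(1, 10, 0.1, 100, 0.01), function(m) {
    list(Mf = max(Mf0, 1e-3), b = min(max(b0 * m, 1e-5), 99),
         c = min(max(c0, -0.49), 0.49))
  })
  fit <- NULL
  for (s in starts) {
    fit <- do_fit(s)
    if (!is.null(fit)) break
  }

  if (is.null(fit)) {
    out <- list(Mf = NA_real_, b = NA_real_, c = NA_real_,
                t_half = NA_real_, residual_rms = NA_real_,
                converged = FALSE, channel = channel, n = length(t),
                data = dat, fit = NULL,
                diagnostics = "nonlinear least squares failed after restarts")
    class(out) <- "frap_fit"
    return(out)
  }
  est <- stats::coef(fit)
  on_bound <- est[["b"]] <= 1e-6 * 1.01 || est[["b"]] >= 100 * 0.999
  flat <- est[["Mf"]] < 1e-3   # no amplitude: rate is unidentifiable
  bad <- on_bound || flat
  out <- list(
    Mf = est[["Mf"]], b = est[["b"]], c = est[["c"]],
    t_half = if (bad) NA_real_ else log(2) / est[["b"]],
    residual_rms = sqrt(mean(stats::resid(fit)^2)),
    converged = !bad,
    channel = channel, n = length(t), data = dat, fit = fit,
    diagnostics = if (bad) "rate constant unidentifiable" else NULL
  )
  class(out) <- "frap_fit"
  out
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential recovery fit (%s channel): Mf = %.4f, t_half = %.3f h, c = %.4f\n",
    x$channel, x$Mf, x$t_half, x$c))
  cat(sprintf("residual RMS %.4g over %d samples; converged: %s\n",
              x$residual_rms, x$n, x$converged))
  invisible(x)
}

#' Compare mobile fraction and half-life between two groups of fits
#'
#' Two-sample Student's t-test (equal variances, two-sided) on the fitted
#' mobile fractions, and separately on the half-lives, of two groups of
#' converged fits.
#'
#' @param fits_a,fits_b Lists of `frap_fit` objects (non-converged fits are
#'   dropped; at least 2 converged fits per group are required).
#' @return A tibble with one row per metric (`Mf`, `t_half`): group means,
#'   standard errors, group sizes, t statistic, degrees of freedom and
#'   two-sided p value.
#' @export
compare_mf <- function(fits_a, fits_b) {
  pull <- function(fits, what) {
    v <- vapply(fits, function(f) {
      if (isTRUE(f$converged)) f[[what]] else NA_real_
    }, numeric(1))
    v[!is.na(v)]
  }
  one <- function(metric) {
    a <- pull(fits_a, metric); b <- pull(fits_b, metric)
    if (length(a) < 2L || length(b) < 2L) {
      stop("insufficient data: need >= 2 converged fits per group",
           call. = FALSE)
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      tt <- list(statistic = c(t = 0), parameter = length(a) + length(b) - 2,
                 p.value = 1)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
    }
    tibble::tibble(
      metric = metric,
      mean_a = mean(a), se_a = stats::sd(a) / sqrt(length(a)), n_a = length(a),
      mean_b = mean(b), se_b = stats::sd(b) / sqrt(length(b)), n_b = length(b),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value
    )
  }
  dplyr::bind_rows(one("Mf"), one("t_half"))
}
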