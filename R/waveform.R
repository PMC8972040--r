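#' Line-scan a two-channel image along a polyline
#'
#' Samples both channels along a polyline at unit-pixel arc-length steps,
#' averaging `width_px` bilinear samples taken perpendicular to the local
#' scan direction, which reproduces the mean-over-width line scan of
#' standard image software. Pixel indices are 0-based; the image is indexed
#' `[row = y, column = x]`.
#'
#' @param image Either a list with matrices `green` and `red`, or a numeric
#'   array `[y, x, channel]` with two channels (green first).
#' @param polyline A matrix or data frame with columns `x` and `y` (pixel
#'   coordinates, 0-based) giving the polyline vertices.
#' @param width_px Scan width in pixels (odd widths are symmetric about the
#'   polyline).
#' @param pixel_size Physical pixel size, micrometres.
#' @return A tibble of class `line_scan` with columns `position_um`,
#'   `green`, `red`.
#' @export
line_scan <- function(image, polyline, width_px = 1, pixel_size = 0.05) {
  if (is.array(image) && length(dim(image)) == 3L) {
    image <- list(green = image[, , 1], red = image[, , 2])
  }
  stopifnot(is.list(image), all(c("green", "red") %in% names(image)),
            is.matrix(image$green), is.matrix(image$red))
  polyline <- as.data.frame(polyline)
  if (!all(c("x", "y") %in% names(polyline))) {
    names(polyline)[1:2] <- c("x", "y")
  }
  if (nrow(polyline) < 2L) stop("polyline needs >= 2 vertices", call. = FALSE)
  width_px <- as.integer(width_px)
  if (width_px < 1L) stop("width_px must be >= 1", call. = FALSE)

  seg <- diff(as.matrix(polyline[, c("x", "y")]))
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) stop("polyline has zero-length segments", call. = FALSE)
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- unique(c(seq(0, total, by = 1), total))

  offsets <- seq_len(width_px) - (width_px + 1) / 2
  ny <- nrow(image$green); nx <- ncol(image$green)

  bilinear <- function(mat, px, py) {
    eps <- 1e-9
    if (any(px < -eps | px > nx - 1 + eps | py < -eps | py > ny - 1 + eps)) {
      stop("polyline (or its width band) falls outside the image",
           call. = FALSE)
    }
    px <- pmin(pmax(px, 0), nx - 1); py <- pmin(pmax(py, 0), ny - 1)
    x0 <- pmin(floor(px), nx - 2); y0 <- pmin(floor(py), ny - 2)
    fx <- px - x0; fy <- py - y0
    # matrix is [y + 1, x + 1] for 0-based (x, y)
    v00 <- mat[cbind(y0 + 1, x0 + 1)]
    v01 <- mat[cbind(y0 + 1, x0 + 2)]
    v10 <- mat[cbind(y0 + 2, x0 + 1)]
    v11 <- mat[cbind(y0 + 2, x0 + 2)]
    v00 * (1 - fx) * (1 - fy) + v01 * fx * (1 - fy) +
      v10 * (1 - fx) * fy + v11 * fx * fy
  }

  sample_channel <- function(mat) {
    vapply(s, function(si) {
      i <- max(1L, min(findInterval(si, cum, rightmost.closed = TRUE),
                       nrow(seg)))
      frac <- (si - cum[i]) / seg_len[i]
      p <- as.numeric(polyline[i, c("x", "y")]) + frac * seg[i, ]
      d <- seg[i, ] / seg_len[i]
      nrm <- c(-d[2], d[1])
      mean(bilinear(mat, p[1] + offsets * nrm[1], p[2] + offsets * nrm[2]))
    }, numeric(1))
  }

  out <- tibble::new_tibble(
    list(position_um = s * pixel_size,
         green = sample_channel(image$green),
         red = sample_channel(image$red)),
    class = "line_scan"
  )
  attr(out, "pixel_size") <- pixel_size
  out
}

#' Replicate a 1-D line scan into a small synthetic image
#'
#' Utility for round-trip testing: stacks a line scan's profile into
#' `height` identical image rows, so a horizontal [line_scan()] through the
#' stack recovers the original profile.
#'
#' @param scan A `line_scan` tibble.
#' @param height Number of image rows.
#' @return A list with matrices `green` and `red`.
#' @export
scan_to_image <- function(scan, height = 5) {
  list(green = matrix(rep(scan$green, each = height), nrow = height),
       red = matrix(rep(scan$red, each = height), nrow = height))
}

# polynomial helpers on coefficient vectors c0 + c1 u + c2 u^2 + ...
polyval_c <- function(coef, u) {
  out <- rep(0, length(u))
  for (j in rev(seq_along(coef))) out <- out * u + coef[j]
  out
}
polyder_c <- function(coef) {
  d <- length(coef) - 1L
  if (d < 1L) return(0)
  coef[-1] * seq_len(d)
}
polyint_c <- function(coef) c(0, coef / seq_along(coef))

#' Fit smoothing polynomials to a line scan
#'
#' Least-squares polynomial fit per channel over the scan window, the
#' smoothing step that turns a pixel profile into the single-peak sarcomere
#' curve used for Z-band detection. Positions are internally centred and
#' scaled for conditioning. A `total` (green + red) channel is fitted as
#' well, available for Z-band detection when the green channel alone does
#' not trace the full filament (e.g. immediately after photoconversion).
#'
#' @param scan A `line_scan` tibble (columns `position_um`, `green`, `red`).
#' @param degree Polynomial degree (0-12; 6 is a good default for a window
#'   of one sarcomere plus its shoulders).
#' @return An object of class `sarcomere_polyfit`.
#' @export
fit_polynomial <- function(scan, degree = 6) {
  stopifnot(is.data.frame(scan),
            all(c("position_um", "green", "red") %in% names(scan)))
  degree <- as.integer(degree)
  if (degree < 0L || degree > 12L) stop("degree must be in 0..12", call. = FALSE)
  x <- scan$position_um
  if (length(x) < degree + 2L) {
    stop("need at least degree + 2 samples", call. = FALSE)
  }
  mu <- mean(x); sdx <- stats::sd(x)
  if (!is.finite(sdx) || sdx == 0) {
    stop("degenerate positions: design is ill-conditioned", call. = FALSE)
  }
  u <- (x - mu) / sdx
  X <- outer(u, 0:degree, "^")
  qrX <- qr(X)
  if (qrX$rank < degree + 1L) {
    stop("degenerate positions: design is ill-conditioned", call. = FALSE)
  }
  fit_one <- function(y) qr.coef(qrX, y)
  coefs <- list(green = fit_one(scan$green),
                red = fit_one(scan$red),
                total = fit_one(scan$green + scan$red))
  structure(
    list(coefs = coefs, mu = mu, sd = sdx, degree = degree,
         u_range = range(u), scan = scan),
    class = "sarcomere_polyfit"
  )
}

#' Evaluate a fitted channel polynomial
#'
#' @param fit A `sarcomere_polyfit`.
#' @param x Positions (micrometres, original scan coordinates).
#' @param channel `"green"`, `"red"` or `"total"`.
#' @return Fitted values at `x`.
#' @export
predict_channel <- function(fit, x, channel = "green") {
  stopifnot(inherits(fit, "sarcomere_polyfit"))
  polyval_c(fit$coefs[[channel]], (x - fit$mu) / fit$sd)
}

#' Locate the Z-band turning points of a fitted sarcomere curve
#'
#' The Z-bands are the two local minima of the fitted curve flanking its
#' principal maximum: the nearest turning points of the fluorescence
#' profile on either side of the sarcomere's peak. Extrema are found at
#' sub-pixel resolution as real roots of the derivative polynomial,
#' classified by the second derivative; ties between equal-height maxima
#' resolve to the leftmost. Only deep minima qualify as Z-band candidates:
#' a minimum must fall below `min_rel_depth` times the principal peak
#' value, which rejects shallow dimples on the filament shoulder (caused by
#' locally replaced label) while keeping the near-background inter-sarcomere
#' gaps.
#'
#' @param fit A `sarcomere_polyfit` from [fit_polynomial()].
#' @param channel Channel whose curve defines the turning points
#'   (`"green"` by default, per the convention that the pre-existing /
#'   structural label traces the sarcomere).
#' @param min_rel_depth Depth qualification for Z-band minima, as a
#'   fraction of the principal peak value.
#' @return A list with `left` and `right` (positions, micrometres), `peak`
#'   (position of the principal maximum) and `value_left`, `value_right`
#'   (fitted values at the turning points).
#' @export
find_turning_points <- function(fit, channel = "green",
                                min_rel_depth = 0.5) {
  stopifnot(inherits(fit, "sarcomere_polyfit"))
  coef <- fit$coefs[[channel]]
  d1 <- polyder_c(coef)
  if (all(d1 == 0)) {
    stop("boundary error: curve has no interior extrema", call. = FALSE)
  }
  d2 <- polyder_c(d1)
  rts <- polyroot(d1)
  tol_im <- 1e-7
  u <- Re(rts[abs(Im(rts)) < tol_im * (1 + abs(Re(rts)))])
  lo <- fit$u_range[1]; hi <- fit$u_range[2]
  span <- hi - lo
  u <- u[u >= lo - 1e-8 * span & u <= hi + 1e-8 * span]
  if (length(u) == 0L) {
    stop("boundary error: curve has no interior extrema", call. = FALSE)
  }
  curv <- polyval_c(d2, u)
  minima <- sort(u[curv > 0])
  maxima <- sort(u[curv < 0])
  interior <- maxima[maxima > lo + 1e-8 * span & maxima < hi - 1e-8 * span]
  if (length(interior) == 0L) {
    stop("boundary error: no interior maximum (sarcomere truncated)",
         call. = FALSE)
  }
  vals <- polyval_c(coef, interior)
  peak <- interior[which(vals >= max(vals) - 1e-12 * abs(max(vals)))][1]
  v_peak <- polyval_c(coef, peak)

  deep <- polyval_c(coef, minima) <= min_rel_depth * v_peak
  minima <- minima[deep]
  left_c <- minima[minima < peak]
  right_c <- minima[minima > peak]
  if (length(left_c) == 0L || length(right_c) == 0L) {
    stop("boundary error: no flanking minima (sarcomere truncated)",
         call. = FALSE)
  }
  l <- max(left_c)        # nearest flanking minimum on each side
  r <- min(right_c)
  list(left = l * fit$sd + fit$mu,
       right = r * fit$sd + fit$mu,
       peak = peak * fit$sd + fit$mu,
       value_left = polyval_c(coef, l),
       value_right = polyval_c(coef, r))
}

#' Extract a normalized two-channel sarcomere waveform
#'
#' Restricts both fitted channels to the turning-point interval, subtracts
#' per channel the straight baseline through that channel's values at the
#' two turning points, rescales each channel to a maximum of 1, and maps the
#' position axis affinely so the interval midpoint (the M-line) is 0 and the
#' turning points (Z-bands) are -1 and +1. The red curve is evaluated at
#' exactly the green-defined positions. Values that fall below the baseline
#' are clipped at 0, so both channels lie in `[0, 1]` and waveform
#' differences lie in `[-1, 1]`.
#'
#' @param fit A `sarcomere_polyfit`.
#' @param turning_points A turning-point list from [find_turning_points()].
#' @param grid_n Number of points of the normalized grid (odd keeps x = 0
#'   on-grid).
#' @param refit Refit the channel polynomials on the scan samples inside
#'   the turning-point interval before evaluation (default). The wide-scan
#'   fit locates the Z-bands robustly, but a polynomial spanning
#'   neighboring sarcomeres underfits structure inside one sarcomere; the
#'   local refit extracts the single-sarcomere peak the way the wide fit
#'   cannot. Falls back to the wide fit when the interval holds too few
#'   samples.
#' @return A tibble of class `sarcomere_waveform` with columns `x_norm`,
#'   `green`, `red`. Pre-normalization channel amplitudes (baseline-removed
#'   maxima, in fitted intensity units) are kept in attributes
#'   `green_scale` and `red_scale`; a channel with no signal above its
#'   baseline is flagged in attribute `empty_channels` and set to 0.
#' @export
extract_sarcomere <- function(fit, turning_points, grid_n = 201,
                              refit = TRUE) {
  stopifnot(inherits(fit, "sarcomere_polyfit"))
  l <- turning_points$left; r <- turning_points$right
  if (!(l < r)) stop("turning points must satisfy left < right", call. = FALSE)
  xr <- range(fit$scan$position_um)
  if (l < xr[1] - 1e-9 || r > xr[2] + 1e-9) {
    stop("turning points outside the scan", call. = FALSE)
  }
  time_min <- attr(fit$scan, "time_min")
  if (refit) {
    inside <- fit$scan$position_um >= l & fit$scan$position_um <= r
    if (sum(inside) >= fit$degree + 2L) {
      fit <- fit_polynomial(fit$scan[inside, ], degree = fit$degree)
    }
  }
  x_norm <- seq(-1, 1, length.out = grid_n)
  mid <- (l + r) / 2; half <- (r - l) / 2
  px <- mid + x_norm * half

  empties <- character(0)
  chan <- function(name) {
    v <- predict_channel(fit, px, name)
    base <- v[1] + (v[grid_n] - v[1]) * (x_norm + 1) / 2
    w <- v - base
    sc <- max(w)
    if (!is.finite(sc) || sc <= 1e-12) {
      empties <<- c(empties, name)
      return(list(values = rep(0, grid_n), scale = 0))
    }
    list(values = pmax(w, 0) / sc, scale = sc)
  }
  g <- chan("green"); rd <- chan("red")

  out <- tibble::new_tibble(
    list(x_norm = x_norm, green = g$values, red = rd$values),
    class = "sarcomere_waveform"
  )
  attr(out, "green_scale") <- g$scale
  attr(out, "red_scale") <- rd$scale
  attr(out, "empty_channels") <- empties
  attr(out, "turning_points") <- turning_points
  attr(out, "degree") <- fit$degree
  attr(out, "time_min") <- time_min
  out
}

#' Line scan to normalized waveform in one step
#'
#' Convenience wrapper chaining [fit_polynomial()], [find_turning_points()]
#' and [extract_sarcomere()].
#'
#' @param scan A `line_scan`.
#' @param degree Polynomial degree.
#' @param tp_channel Channel used for turning-point detection.
#' @param grid_n Normalized grid size.
#' @return A `sarcomere_waveform`.
#' @export
scan_to_waveform <- function(scan, degree = 6, tp_channel = "green",
                             grid_n = 201) {
  fit <- fit_polynomial(scan, degree = degree)
  tp <- find_turning_points(fit, channel = tp_channel)
  extract_sarcomere(fit, tp, grid_n = grid_n)
}

#' Red minus green difference profile of one waveform
#'
#' @param w A `sarcomere_waveform`.
#' @return A tibble with columns `x_norm` and `diff` (normalized red minus
#'   normalized green). Because both channels are max-normalized, this is a
#'   shape comparison, not an abundance comparison.
#' @export
subtract_waveforms <- function(w) {
  stopifnot(is.data.frame(w), all(c("x_norm", "green", "red") %in% names(w)))
  tibble::tibble(x_norm = w$x_norm, diff = w$red - w$green)
}

#' Collect sarcomere waveforms into a long table
#'
#' @param waveforms A list of `sarcomere_waveform` objects (attributes
#'   `sarcomere_id`, `myotube`, `time_min` are carried into columns when
#'   present).
#' @return A long tibble with columns `sarcomere_id`, `myotube`,
#'   `time_min`, `x_norm`, `green`, `red`.
#' @export
waveform_table <- function(waveforms) {
  dplyr::bind_rows(lapply(seq_along(waveforms), function(i) {
    w <- waveforms[[i]]
    tibble::tibble(
      sarcomere_id = attr(w, "sarcomere_id") %||% i,
      myotube = attr(w, "myotube") %||% NA_integer_,
      time_min = attr(w, "time_min") %||% NA_real_,
      x_norm = w$x_norm, green = w$green, red = w$red
    )
  }))
}

#' Build a red minus green difference map over time
#'
#' For every time point the supplied waveforms are averaged per channel
#' across sarcomeres on the common normalized grid, and the mean green
#' waveform is subtracted from the mean red waveform. The result is the
#' time-by-position matrix whose sign shows where newly inserted (or
#' remaining converted) label dominates.
#'
#' @param waveforms A list of `sarcomere_waveform` objects or a long tibble
#'   with columns `time_min`, `x_norm`, `green`, `red`.
#' @return A tibble of class `difference_map` with columns `time_min`,
#'   `x_norm`, `diff`, ordered by time. Values always lie in `[-1, 1]`.
#' @export
build_difference_map <- function(waveforms) {
  if (is.list(waveforms) && !is.data.frame(waveforms)) {
    waveforms <- waveform_table(waveforms)
  }
  stopifnot(all(c("time_min", "x_norm", "green", "red") %in% names(waveforms)))
  grids <- waveforms |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(n_x = dplyr::n_distinct(.data$x_norm), .groups = "drop")
  if (length(unique(grids$n_x)) > 1L) {
    warning("waveform grids differ; resampling to the first grid")
    ref <- sort(unique(waveforms$x_norm[
      waveforms$time_min == waveforms$time_min[1]]))
    waveforms <- waveforms |>
      dplyr::group_by(.data$time_min, .data$sarcomere_id) |>
      dplyr::reframe(
        x_norm = ref,
        green = stats::approx(.data$x_norm, .data$green, ref, rule = 2)$y,
        red = stats::approx(.data$x_norm, .data$red, ref, rule = 2)$y
      )
  }
  out <- waveforms |>
    dplyr::group_by(.data$time_min, .data$x_norm) |>
    dplyr::summarise(green = mean(.data$green), red = mean(.data$red),
                     .groups = "drop") |>
    dplyr::mutate(diff = .data$red - .data$green) |>
    dplyr::select("time_min", "x_norm", "diff") |>
    dplyr::arrange(.data$time_min, .data$x_norm)
  class(out) <- c("difference_map", class(out))
  out
}
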