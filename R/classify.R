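#' The eight incorporation-pattern categories
#'
#' Ordered factor levels for the red-peak incorporation patterns: both
#' sides, predominantly right side, predominantly left side, right side,
#' left side, center, random fashion, and no incorporation.
#'
#' @return Character vector of the eight category names.
#' @export
pattern_categories <- function() {
  c("both_sides", "predominantly_right", "predominantly_left",
    "right_side", "left_side", "center", "random_fashion",
    "no_incorporation")
}

side_categories <- function() {
  c("both_sides", "predominantly_right", "predominantly_left",
    "right_side", "left_side")
}

#' Decision thresholds for incorporation-pattern classification
#'
#' The categories themselves are qualitative; these thresholds make them
#' operational. All are recorded in classification output so every decision
#' is reproducible.
#'
#' @param center_zone_halfwidth Half-width of the central zone in
#'   normalized x: a principal peak with `|x|` below this is a center
#'   pattern.
#' @param side_zone_min Minimum `|x|` for a peak to count as a side peak.
#' @param balance_ratio Minimum height ratio (smaller/taller) for two side
#'   peaks to count as balanced ("both sides"); below it the pattern is
#'   "predominantly" the taller peak's side.
#' @param shape_similarity_min Minimum red-green correlation for the red
#'   and green signal patterns to be considered identical (random fashion).
#' @param red_signal_floor Minimum red dynamic range, as a fraction of the
#'   green dynamic range, below which a sarcomere shows no incorporation.
#' @param peak_prominence_min Minimum peak prominence, as a fraction of the
#'   channel maximum, for a local maximum to count as a peak.
#' @param peak_x_max Maximum `|x|` for a qualifying peak. Fluorescence
#'   beyond the green-supported filament extent (tips near 0.8 under the
#'   default geometry) cannot come from filament-incorporated myosin, so
#'   apparent peaks outside this bound are treated as baseline or fitting
#'   artifacts.
#' @return An object of class `classification_rules`.
#' @export
classification_rules <- function(center_zone_halfwidth = 0.25,
                                 side_zone_min = 0.40,
                                 balance_ratio = 0.60,
                                 shape_similarity_min = 0.90,
                                 red_signal_floor = 0.15,
                                 peak_prominence_min = 0.20,
                                 peak_x_max = 0.85) {
  if (!(center_zone_halfwidth > 0 && center_zone_halfwidth < side_zone_min &&
        side_zone_min < 1)) {
    stop("require 0 < center_zone_halfwidth < side_zone_min < 1",
         call. = FALSE)
  }
  if (!(balance_ratio > 0 && balance_ratio <= 1)) {
    stop("balance_ratio must be in (0, 1]", call. = FALSE)
  }
  if (!(shape_similarity_min > 0 && shape_similarity_min < 1)) {
    stop("shape_similarity_min must be in (0, 1)", call. = FALSE)
  }
  if (!(peak_x_max > side_zone_min)) {
    stop("peak_x_max must exceed side_zone_min", call. = FALSE)
  }
  structure(
    list(center_zone_halfwidth = center_zone_halfwidth,
         side_zone_min = side_zone_min,
         balance_ratio = balance_ratio,
         shape_similarity_min = shape_similarity_min,
         red_signal_floor = red_signal_floor,
         peak_prominence_min = peak_prominence_min,
         peak_x_max = peak_x_max),
    class = "classification_rules"
  )
}

# local maxima with topographic prominence on a regular grid
grid_peaks <- function(x, y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  idx <- idx[y[idx] > y[pmax(idx - 1L, 1L)] | y[idx] > y[pmin(idx + 1L, n)]]
  if (length(idx) == 0L) {
    return(tibble::tibble(position = numeric(0), height = numeric(0),
                          prominence = numeric(0)))
  }
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1L)]
    higher_l <- which(left >= h)
    base_l <- if (length(higher_l)) {
      min(left[(max(higher_l)):(i - 1L)])
    } else min(left)
    right <- y[(i + 1L):n]
    higher_r <- which(right >= h)
    base_r <- if (length(higher_r)) {
      min(right[seq_len(min(higher_r))])
    } else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  tibble::tibble(position = x[idx], height = y[idx], prominence = prom)
}

#' Detect red-channel peaks in a normalized waveform
#'
#' Local maxima of the normalized red curve with topographic prominence of
#' at least `peak_prominence_min` (the channel maximum is 1, so the
#' threshold is on the normalized scale), sorted outermost first.
#'
#' @param w A `sarcomere_waveform`.
#' @param rules A [classification_rules()].
#' @return A tibble with columns `position`, `height`, `prominence`,
#'   ordered by decreasing `|position|`. Empty when the red channel has no
#'   qualifying peak.
#' @export
detect_red_peaks <- function(w, rules = classification_rules()) {
  stopifnot(is.data.frame(w), all(c("x_norm", "red") %in% names(w)))
  pk <- grid_peaks(w$x_norm, w$red)
  pk <- pk[pk$prominence >= rules$peak_prominence_min &
             abs(pk$position) <= rules$peak_x_max, , drop = FALSE]
  pk[order(abs(pk$position), decreasing = TRUE), , drop = FALSE]
}

#' Classify a sarcomere's incorporation pattern
#'
#' Applies the decision cascade assigning one of the eight red-peak
#' categories:
#'
#' 1. **no incorporation** - the red dynamic range (pre-normalization) is
#'    below `red_signal_floor` times the green dynamic range;
#' 2. **random fashion** - the red and green signal patterns are identical
#'    (correlation at least `shape_similarity_min`) and no side peak rises
#'    above the green curve by the prominence threshold;
#' 3. side peaks in both side zones: **both sides** if their heights are
#'    balanced (ratio at least `balance_ratio`), otherwise **predominantly**
#'    the taller side;
#' 4. side peak(s) on one side only: **right side** / **left side**;
#' 5. a single principal peak inside the center zone: **center**;
#' 6. anything unresolved falls back to **random fashion**, flagged low
#'    confidence.
#'
#' @param w A `sarcomere_waveform`.
#' @param rules A [classification_rules()].
#' @return A one-row tibble: `sarcomere_id`, `myotube`, `time_min`,
#'   `category`, `similarity`, `range_ratio`, `n_peaks`, `low_confidence`,
#'   and a list-column `peaks` with the detected red peaks.
#' @export
classify_pattern <- function(w, rules = classification_rules()) {
  stopifnot(is.data.frame(w), all(c("x_norm", "green", "red") %in% names(w)))
  gs <- attr(w, "green_scale") %||% 1
  rs <- attr(w, "red_scale") %||% 1
  empty <- attr(w, "empty_channels") %||% character(0)
  range_ratio <- if (gs > 0) rs / gs else Inf
  similarity <- suppressWarnings(stats::cor(w$red, w$green))
  peaks <- detect_red_peaks(w, rules)
  side <- peaks[abs(peaks$position) >= rules$side_zone_min, , drop = FALSE]

  low_confidence <- FALSE
  category <- NULL
  if ("red" %in% empty || range_ratio < rules$red_signal_floor) {
    category <- "no_incorporation"
  } else {
    green_at <- function(p) {
      w$green[which.min(abs(w$x_norm - p))]
    }
    side_over_green <- nrow(side) > 0 &&
      any(side$height - vapply(side$position, green_at, numeric(1)) >=
            rules$peak_prominence_min)
    if (!is.na(similarity) && similarity >= rules$shape_similarity_min &&
        !side_over_green) {
      category <- "random_fashion"
    } else {
      has_l <- any(side$position <= -rules$side_zone_min)
      has_r <- any(side$position >= rules$side_zone_min)
      if (has_l && has_r) {
        hl <- max(side$height[side$position <= -rules$side_zone_min])
        hr <- max(side$height[side$position >= rules$side_zone_min])
        ratio <- min(hl, hr) / max(hl, hr)
        category <- if (ratio >= rules$balance_ratio) {
          "both_sides"
        } else if (hr > hl) "predominantly_right" else "predominantly_left"
      } else if (has_l || has_r) {
        category <- if (has_r) "right_side" else "left_side"
      } else if (nrow(peaks) > 0) {
        principal <- peaks$position[which.max(peaks$height)]
        if (abs(principal) <= rules$center_zone_halfwidth) {
          category <- "center"
        }
      }
      if (is.null(category)) {
        category <- "random_fashion"
        low_confidence <- TRUE
      }
    }
  }

  tibble::tibble(
    sarcomere_id = attr(w, "sarcomere_id") %||% NA_integer_,
    myotube = attr(w, "myotube") %||% NA_integer_,
    time_min = attr(w, "time_min") %||% NA_real_,
    category = factor(category, levels = pattern_categories()),
    similarity = similarity,
    range_ratio = range_ratio,
    n_peaks = nrow(peaks),
    low_confidence = low_confidence,
    peaks = list(peaks)
  )
}

#' Classify a population of sarcomere waveforms
#'
#' @param waveforms A list of `sarcomere_waveform` objects, or a
#'   `pulse_chase_population` from [generate_pulse_chase_population()] (in
#'   which case the ground-truth categories are joined in as
#'   `truth_category`).
#' @param rules A [classification_rules()].
#' @return A tibble with one classification row per sarcomere.
#' @export
classify_patterns <- function(waveforms, rules = classification_rules()) {
  truth <- NULL
  if (inherits(waveforms, "pulse_chase_population")) {
    truth <- waveforms$truth
    waveforms <- waveforms$waveforms
  }
  out <- dplyr::bind_rows(lapply(waveforms, classify_pattern, rules = rules))
  if (!is.null(truth)) {
    out <- dplyr::left_join(
      out, truth[, c("sarcomere_id", "truth_category")],
      by = "sarcomere_id")
  }
  out
}

#' Peak-shift records for a side-pattern sarcomere
#'
#' For waveforms in the five side categories, the distance between each
#' qualifying side-zone red peak and the sarcomere center, `|x_peak|`, one
#' record per peak. The subcategory groups the five patterns into the three
#' reported classes: both sides, predominantly (right + left), one side
#' (right + left).
#'
#' @param classified A one-row classification tibble from
#'   [classify_pattern()].
#' @return A tibble with columns `sarcomere_id`, `time_min`, `category`,
#'   `subcategory`, `peak_x`, `shift`.
#' @export
peak_shift <- function(classified) {
  stopifnot(is.data.frame(classified), nrow(classified) == 1L)
  cat <- as.character(classified$category)
  if (!cat %in% side_categories()) {
    stop(sprintf("category error: peak_shift applies to side patterns, not '%s'",
                 cat), call. = FALSE)
  }
  rules_side <- attr(classified, "side_zone_min") %||% 0.40
  pk <- classified$peaks[[1]]
  pk <- pk[abs(pk$position) >= rules_side, , drop = FALSE]
  sub <- switch(cat,
                both_sides = "both_sides",
                predominantly_right = , predominantly_left = "predominantly",
                right_side = , left_side = "one_side")
  tibble::tibble(
    sarcomere_id = classified$sarcomere_id,
    time_min = classified$time_min,
    category = cat, subcategory = sub,
    peak_x = pk$position, shift = abs(pk$position)
  )
}

#' Peak-shift records for every side-pattern sarcomere in a table
#'
#' @param classified A classification tibble from [classify_patterns()];
#'   non-side categories are skipped.
#' @return A long tibble of peak-shift records (possibly empty).
#' @export
peak_shifts <- function(classified) {
  keep <- as.character(classified$category) %in% side_categories()
  rows <- lapply(which(keep), function(i) peak_shift(classified[i, ]))
  if (length(rows) == 0L) {
    return(tibble::tibble(sarcomere_id = integer(0), time_min = numeric(0),
                          category = character(0), subcategory = character(0),
                          peak_x = numeric(0), shift = numeric(0)))
  }
  dplyr::bind_rows(rows)
}

#' Summarize incorporation patterns across myotubes and time points
#'
#' Computes per-myotube category proportions and their mean and standard
#' error across myotubes for every time point, a stacked-group rollup (side
#' group = both sides + predominantly + one side; center; random fashion;
#' no incorporation), peak-shift histograms and the median peak shift per
#' time point.
#'
#' @param classified A classification tibble from [classify_patterns()]
#'   with `myotube` and `time_min` columns filled in.
#' @param bin_width Histogram bin width on the normalized shift axis.
#' @return An object of class `pattern_summary`: a list with tibbles
#'   `frequency` (per time point and category: mean proportion, SE, n),
#'   `rollup`, `peak_shift` (the raw records), `histogram` and `medians`.
#' @export
summarize_patterns <- function(classified, bin_width = 0.05) {
  stopifnot(all(c("myotube", "time_min", "category") %in% names(classified)))
  classified <- classified[!is.na(classified$myotube), ]
  if (nrow(classified) == 0L) stop("no classified sarcomeres", call. = FALSE)

  per_myotube <- classified |>
    dplyr::count(.data$time_min, .data$myotube, .data$category) |>
    tidyr::complete(
      tidyr::nesting(time_min, myotube),
      category = factor(pattern_categories(), levels = pattern_categories()),
      fill = list(n = 0L)
    ) |>
    dplyr::group_by(.data$time_min, .data$myotube) |>
    dplyr::mutate(prop = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$time_min))

  frequency <- per_myotube |>
    dplyr::group_by(.data$time_min, .data$category) |>
    dplyr::summarise(
      mean_prop = mean(.data$prop),
      se = stats::sd(.data$prop) / sqrt(dplyr::n()),
      n_myotubes = dplyr::n(),
      n_sarcomeres = sum(.data$n),
      .groups = "drop"
    )

  group_of <- function(cat) {
    dplyr::case_when(
      cat %in% side_categories() ~ "side_group",
      cat == "center" ~ "center",
      cat == "random_fashion" ~ "random_fashion",
      TRUE ~ "no_incorporation"
    )
  }
  rollup <- per_myotube |>
    dplyr::mutate(group = group_of(as.character(.data$category))) |>
    dplyr::group_by(.data$time_min, .data$myotube, .data$group) |>
    dplyr::summarise(prop = sum(.data$prop), .groups = "drop") |>
    dplyr::group_by(.data$time_min, .data$group) |>
    dplyr::summarise(
      mean_prop = mean(.data$prop),
      se = stats::sd(.data$prop) / sqrt(dplyr::n()),
      n_myotubes = dplyr::n(),
      .groups = "drop"
    )

  shifts <- peak_shifts(classified)
  breaks <- seq(0, 1, by = bin_width)
  histogram <- if (nrow(shifts) > 0) {
    shifts |>
      dplyr::mutate(bin = cut(pmin(.data$shift, 1 - 1e-12), breaks,
                              right = FALSE, include.lowest = TRUE)) |>
      dplyr::count(.data$time_min, .data$subcategory, .data$bin,
                   name = "count") |>
      dplyr::mutate(bin_mid = breaks[as.integer(.data$bin)] + bin_width / 2)
  } else {
    tibble::tibble(time_min = numeric(0), subcategory = character(0),
                   bin = factor(), count = integer(0), bin_mid = numeric(0))
  }
  medians <- if (nrow(shifts) > 0) {
    shifts |>
      dplyr::group_by(.data$time_min) |>
      dplyr::summarise(median_shift = stats::median(.data$shift),
                       n_peaks = dplyr::n(), .groups = "drop")
  } else {
    tibble::tibble(time_min = numeric(0), median_shift = numeric(0),
                   n_peaks = integer(0))
  }

  structure(
    list(frequency = frequency, rollup = rollup, peak_shift = shifts,
         histogram = histogram, medians = medians, bin_width = bin_width),
    class = "pattern_summary"
  )
}
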