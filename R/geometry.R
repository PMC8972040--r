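#' Bipolar thick-filament geometry
#'
#' Describes a single thick filament inside one sarcomere. The filament is
#' bipolar and centred on the M-line; myosin sites are placed symmetrically,
#' evenly spaced along each half-filament. Axial positions are expressed in
#' the normalized sarcomere coordinate in which the M-line is 0 and the
#' Z-bands sit at -1 and +1, so the filament tips fall at
#' `+/- filament_length / sarcomere_length` (0.8 with the defaults, matching
#' the position at which fluorescence support ends in normalized line scans).
#'
#' @param filament_length Thick-filament length in micrometres.
#' @param sarcomere_length Sarcomere length (Z-band to Z-band) in micrometres.
#' @param n_myosins Total number of myosin sites on the filament; must be an
#'   even count so the two half-filaments are identical.
#'
#' @return An object of class `filament_geometry`: a list with the three
#'   parameters plus `x`, the sorted vector of normalized site positions, and
#'   `x_tip`, the normalized tip coordinate.
#' @examples
#' geom <- filament_geometry()
#' geom$x_tip            # 0.8
#' range(geom$x)
#' @export
filament_geometry <- function(filament_length = 1.6,
                              sarcomere_length = 2.0,
                              n_myosins = 300) {
  if (!is.numeric(filament_length) || filament_length <= 0 ||
      !is.numeric(sarcomere_length) || sarcomere_length <= 0) {
    stop("filament_length and sarcomere_length must be positive", call. = FALSE)
  }
  if (filament_length >= sarcomere_length) {
    stop("filament_length must be smaller than sarcomere_length", call. = FALSE)
  }
  n_myosins <- as.integer(n_myosins)
  if (is.na(n_myosins) || n_myosins < 2 || n_myosins %% 2L != 0L) {
    stop("n_myosins must be an even integer >= 2", call. = FALSE)
  }
  x_tip <- filament_length / sarcomere_length
  n_half <- n_myosins %/% 2L
  # midpoint placement keeps sites strictly inside (0, x_tip]
  half <- x_tip * (seq_len(n_half) - 0.5) / n_half
  x <- sort(c(-half, half))
  structure(
    list(filament_length = filament_length,
         sarcomere_length = sarcomere_length,
         n_myosins = n_myosins,
         x = x,
         x_tip = x_tip),
    class = "filament_geometry"
  )
}

#' Labeling protocol for an exchange simulation
#'
#' Two protocols are supported. `"photoconversion"` flips every currently
#' incorporated label from green to red at `event_time` and sets the label of
#' incoming (newly inserted) myosin to green from then on, so green recovery
#' reports insertion and red loss reports release. `"pulse_chase"` leaves the
#' pre-existing pool green and labels myosin inserted after `event_time` red,
#' mimicking sequential ligand labeling of newly synthesized protein.
#'
#' @param mode `"photoconversion"` or `"pulse_chase"`.
#' @param event_time Time of the conversion / chase start, in hours.
#' @return An object of class `label_protocol`.
#' @export
label_protocol <- function(mode = c("photoconversion", "pulse_chase"),
                           event_time = 0) {
  mode <- match.arg(mode)
  if (!is.numeric(event_time) || length(event_time) != 1L || is.na(event_time)) {
    stop("event_time must be a single number (hours)", call. = FALSE)
  }
  structure(list(mode = mode, event_time = event_time),
            class = "label_protocol")
}

#' Rendering / acquisition artifact configuration
#'
#' Parameters of the synthetic optics and detector used when turning
#' simulated label states into fluorescence traces and line scans. The
#' artifacts mirror the ones the analysis side corrects for: a multiplicative
#' photobleaching decay on the green channel (removed by reference-region
#' normalization) and a slow additive linear drift on the red channel
#' (removed by the late-window slope correction).
#'
#' @param pixel_size Line-scan sampling interval, micrometres.
#' @param psf_sigma Gaussian point-spread sigma, micrometres.
#' @param noise_sd Additive Gaussian noise, as a fraction of the signal peak.
#' @param background Uniform background level, as a fraction of the peak.
#' @param bleach_rate_green Green photobleaching rate, fraction per hour.
#' @param red_linear_drift Additive red drift, fraction of peak per minute
#'   (a positive value drifts the converted-ROI red intensity downward).
#' @param intensity_scale Arbitrary-unit scale applied to rendered traces.
#' @return An object of class `render_config`.
#' @export
render_config <- function(pixel_size = 0.05,
                          psf_sigma = 0.1,
                          noise_sd = 0.02,
                          background = 0.05,
                          bleach_rate_green = 0,
                          red_linear_drift = 0,
                          intensity_scale = 100) {
  vals <- c(pixel_size = pixel_size, psf_sigma = psf_sigma,
            noise_sd = noise_sd, background = background,
            bleach_rate_green = bleach_rate_green,
            red_linear_drift = red_linear_drift,
            intensity_scale = intensity_scale)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("render_config parameters must be finite and non-negative",
         call. = FALSE)
  }
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  structure(as.list(vals), class = "render_config")
}
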