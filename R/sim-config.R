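#' Default post-stimulation activity levels
#'
#' Three firing regimes used by the simulated activity patterns. High activity
#' is a 10 Hz event rate with a 25\% chance that an event is a burst of 2--5
#' spikes; medium is 10 Hz with a 1-in-15 burst chance; low is 5 Hz with a
#' 1-in-20 burst chance.
#'
#' @return data.frame with columns `level`, `rate_hz`, `burst_prob`,
#'   `burst_min`, `burst_max`.
#' @export
activity_levels <- function() {
  data.frame(
    level      = c("high", "medium", "low"),
    rate_hz    = c(10, 10, 5),
    burst_prob = c(0.25, 1 / 15, 0.05),
    burst_min  = 2L,
    burst_max  = 5L,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for lensless calcium imaging datasets
#'
#' Describes the synthetic study design: a 120 x 40 pixel sensor recording at
#' ~10 fps, 9,000 pre-stimulation frames (15 min) followed by 36,000
#' post-stimulation frames (60 min), and 30 point-source neurons placed
#' uniformly at integer positions x in \[5, 35\], y in \[5, 115\] (0-based,
#' origin at the top-left pixel) and depth z in \[4, 8\] pixels above the
#' sensor. At 7.5 um per pixel the depth range corresponds to 30--60 um;
#' closer neurons are assumed damaged by implantation and are not simulated.
#' The 5-pixel sensor border is avoided because it is the noisiest part of
#' the device.
#'
#' During pre-stimulation frames every neuron fires spontaneously with
#' per-frame probability `spontaneous_fire_prob`. Post-stimulation, each
#' neuron follows one of three patterns (assigned uniformly at random):
#' pattern 1 is high activity for the first sixth of the post window, medium
#' for the next two sixths, low for the rest; pattern 2 starts at medium,
#' is high in the second sixth, then medium and low; unresponsive neurons
#' keep their spontaneous statistics. At the default 60-min post window the
#' sixths are 10-minute blocks.
#'
#' Rendering parameters (`spike_amplitude`, `baseline_offset`, `noise_sd`,
#' `gradient_amplitude`, `decay_tau_s`, `psf_radius_factor`) control the
#' point-source image model; see [render_frames()]. Their defaults place the
#' deepest neurons near the detection limit of the ROI algorithm so that
#' detection failures are depth-dependent, mirroring the lensless devices'
#' behavior.
#'
#' @param height_px,width_px sensor size in pixels (long axis first).
#' @param fps frame rate, frames per second.
#' @param n_pre_frames,n_post_frames frames before / after stimulation.
#' @param n_neurons number of simulated neurons.
#' @param x_range,y_range inclusive integer bounds for neuron centers,
#'   0-based pixel coordinates; must keep a 5-pixel border.
#' @param z_range_px inclusive integer depth bounds in pixels.
#' @param pixel_pitch_um physical pixel pitch, micrometers.
#' @param spontaneous_fire_prob per-frame spontaneous spike probability.
#' @param pattern_params data.frame of activity levels, see
#'   [activity_levels()].
#' @param decay_tau_s calcium transient decay constant, seconds.
#' @param spike_amplitude brightness scale of a single spike in detector
#'   units (the peak pixel of a spike at depth z is
#'   `spike_amplitude / z^2`).
#' @param baseline_offset constant detector offset, detector units.
#' @param noise_sd standard deviation of additive per-pixel Gaussian noise.
#' @param background_noise_sd stationary standard deviation of the
#'   slowly varying stray-light fluctuation shared by all pixels
#'   (AR(1) with time constant `background_tau_s`). Lensless devices pick
#'   up non-stationary stray light in every pixel; this term is what makes
#'   non-ROI pixels a meaningful noise reference for spectral subtraction.
#' @param background_tau_s correlation time of the shared background
#'   fluctuation, seconds.
#' @param gradient_amplitude amplitude of the static linear illumination
#'   gradient along the long axis (emulating uneven LED excitation).
#' @param psf_radius_factor the point-spread footprint is truncated at
#'   `psf_radius_factor * z` pixels from the source.
#' @param seed integer seed making the dataset reproducible.
#' @return object of class `sim_config` (a validated list).
#' @seealso [simulate_dataset()]
#' @export
sim_config <- function(height_px = 120L, width_px = 40L, fps = 10,
                       n_pre_frames = 9000L, n_post_frames = 36000L,
                       n_neurons = 30L,
                       x_range = c(5L, 35L), y_range = c(5L, 115L),
                       z_range_px = c(4L, 8L), pixel_pitch_um = 7.5,
                       spontaneous_fire_prob = 0.1,
                       pattern_params = activity_levels(),
                       decay_tau_s = 1.0,
                       spike_amplitude = 120,
                       baseline_offset = 100,
                       noise_sd = 1,
                       background_noise_sd = 2,
                       background_tau_s = 5,
                       gradient_amplitude = 10,
                       psf_radius_factor = 4,
                       seed = NULL) {
  check_scalar_number(height_px, "height_px", 1, Inf, integer = TRUE)
  check_scalar_number(width_px, "width_px", 1, Inf, integer = TRUE)
  check_scalar_number(fps, "fps", lower = 1e-9)
  check_scalar_number(n_pre_frames, "n_pre_frames", 1, Inf, integer = TRUE)
  check_scalar_number(n_post_frames, "n_post_frames", 1, Inf, integer = TRUE)
  check_scalar_number(n_neurons, "n_neurons", 0, Inf, integer = TRUE)
  check_scalar_number(spontaneous_fire_prob, "spontaneous_fire_prob", 0, 1)
  check_scalar_number(decay_tau_s, "decay_tau_s", lower = 1e-9)
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(background_noise_sd, "background_noise_sd", lower = 0)
  check_scalar_number(background_tau_s, "background_tau_s", lower = 1e-9)
  check_scalar_number(spike_amplitude, "spike_amplitude", lower = 0)
  check_scalar_number(baseline_offset, "baseline_offset", lower = 0)
  check_scalar_number(psf_radius_factor, "psf_radius_factor", lower = 1e-9)

  check_range <- function(rng, name, lo, hi) {
    if (length(rng) != 2L || any(rng != round(rng)) || rng[1L] > rng[2L]) {
      stopf("'%s' must be an inclusive integer range c(lo, hi)", name)
    }
    if (rng[1L] < lo || rng[2L] > hi) {
      stopf("'%s' = [%d, %d] outside the allowed [%d, %d]",
            name, rng[1L], rng[2L], lo, hi)
    }
    as.integer(rng)
  }
  # neuron centers must keep the noisy 5-px sensor border clear
  x_range <- check_range(x_range, "x_range", 5L, width_px - 5L)
  y_range <- check_range(y_range, "y_range", 5L, height_px - 5L)
  z_range_px <- check_range(z_range_px, "z_range_px", 1L, .Machine$integer.max)

  need <- c("level", "rate_hz", "burst_prob", "burst_min", "burst_max")
  if (!is.data.frame(pattern_params) || !all(need %in% names(pattern_params))) {
    stopf("'pattern_params' must have columns %s", paste(need, collapse = ", "))
  }
  if (!all(c("high", "medium", "low") %in% pattern_params$level)) {
    stopf("'pattern_params' must define levels high, medium and low")
  }
  if (any(pattern_params$rate_hz < 0) ||
      any(pattern_params$burst_prob < 0 | pattern_params$burst_prob > 1) ||
      any(pattern_params$burst_min > pattern_params$burst_max) ||
      any(pattern_params$burst_min < 1)) {
    stopf("invalid 'pattern_params' (rates >= 0, burst_prob in [0,1], burst sizes >= 1)")
  }

  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    fps = fps,
    n_pre_frames = as.integer(n_pre_frames),
    n_post_frames = as.integer(n_post_frames),
    n_neurons = as.integer(n_neurons),
    x_range = x_range, y_range = y_range, z_range_px = z_range_px,
    pixel_pitch_um = pixel_pitch_um,
    spontaneous_fire_prob = spontaneous_fire_prob,
    pattern_params = pattern_params,
    decay_tau_s = decay_tau_s,
    spike_amplitude = spike_amplitude,
    baseline_offset = baseline_offset,
    noise_sd = noise_sd,
    background_noise_sd = background_noise_sd,
    background_tau_s = background_tau_s,
    gradient_amplitude = gradient_amplitude,
    psf_radius_factor = psf_radius_factor,
    seed = seed
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Lensless calcium imaging simulation config\n")
  cat(sprintf("  sensor: %d x %d px at %g fps (%g um/px)\n",
              x$height_px, x$width_px, x$fps, x$pixel_pitch_um))
  cat(sprintf("  frames: %d pre + %d post\n", x$n_pre_frames, x$n_post_frames))
  cat(sprintf("  neurons: %d at x=[%d,%d], y=[%d,%d], z=[%d,%d] px\n",
              x$n_neurons, x$x_range[1], x$x_range[2],
              x$y_range[1], x$y_range[2],
              x$z_range_px[1], x$z_range_px[2]))
  cat(sprintf("  spontaneous p=%g/frame, tau=%gs, amp=%g, noise_sd=%g, seed=%s\n",
              x$spontaneous_fire_prob, x$decay_tau_s, x$spike_amplitude,
              x$noise_sd, x$seed %||% "NULL"))
  invisible(x)
}

#' Per-frame activity level schedule for one pattern
#'
#' Splits the post-stimulation window into sixths. Pattern 1: high for 1/6,
#' medium for 2/6, low for 3/6. Pattern 2: medium, high, medium (2/6),
#' low (2/6). Unresponsive: spontaneous throughout.
#'
#' @param pattern `"pattern1"`, `"pattern2"` or `"unresponsive"`.
#' @param n_post_frames length of the post-stimulation window in frames.
#' @return character vector of length `n_post_frames` with values in
#'   `c("high", "medium", "low", "spontaneous")`.
#' @export
pattern_schedule <- function(pattern, n_post_frames) {
  n_post_frames <- as.integer(n_post_frames)
  if (n_post_frames < 1L) stopf("'n_post_frames' must be >= 1")
  blocks <- switch(pattern,
    pattern1     = list(levels = c("high", "medium", "low"),
                        frac   = c(1, 2, 3) / 6),
    pattern2     = list(levels = c("medium", "high", "medium", "low"),
                        frac   = c(1, 1, 2, 2) / 6),
    unresponsive = list(levels = "spontaneous", frac = 1),
    stopf("unknown pattern '%s'", pattern)
  )
  cuts <- round(cumsum(blocks$frac) * n_post_frames)
  lens <- diff(c(0L, cuts))
  if (sum(lens) != n_post_frames) stopf("schedule does not cover the post window")
  rep(blocks$levels, times = lens)
}
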