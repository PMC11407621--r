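#' Sample ground-truth neuron positions and activity patterns
#'
#' Draws `n_neurons` point-source neurons uniformly at integer pixel positions
#' inside the configured x/y ranges (0-based coordinates, origin at the
#' top-left pixel) and integer depths inside `z_range_px`. Each neuron is
#' assigned one of the three post-stimulation activity patterns uniformly at
#' random. Uses the current RNG stream; seed the stream (or use
#' [simulate_dataset()]) for reproducibility.
#'
#' @param config a [sim_config()].
#' @return data.frame of class `neuron_spec` with columns `id`, `x_px`,
#'   `y_px`, `z_px`, `z_um`, `pattern`.
#' @export
sample_neurons <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_neurons
  neurons <- data.frame(
    id   = seq_len(n),
    x_px = if (n) sample(seq.int(config$x_range[1], config$x_range[2]), n,
                         replace = TRUE) else integer(0),
    y_px = if (n) sample(seq.int(config$y_range[1], config$y_range[2]), n,
                         replace = TRUE) else integer(0),
    z_px = if (n) sample(seq.int(config$z_range_px[1], config$z_range_px[2]),
                         n, replace = TRUE) else integer(0),
    stringsAsFactors = FALSE
  )
  neurons$z_um <- neurons$z_px * config$pixel_pitch_um
  neurons$pattern <- if (n) {
    sample(c("pattern1", "pattern2", "unresponsive"), n, replace = TRUE)
  } else {
    character(0)
  }
  class(neurons) <- c("neuron_spec", "data.frame")
  neurons
}

# spike counts for one homogeneous segment of an activity level:
# events per frame ~ Poisson(rate_hz / fps); each event is a burst with
# probability burst_prob, contributing a uniform integer in
# [burst_min, burst_max] spikes, otherwise a single spike.
draw_level_spikes <- function(n_frames, level_row, fps) {
  ev <- rpois(n_frames, level_row$rate_hz / fps)
  counts <- integer(n_frames)
  total <- sum(ev)
  if (total == 0L) return(counts)
  sz <- rep(1L, total)
  burst <- runif(total) < level_row$burst_prob
  nb <- sum(burst)
  if (nb > 0L) {
    sz[burst] <- sample(seq.int(level_row$burst_min, level_row$burst_max),
                        nb, replace = TRUE)
  }
  frame_of <- rep(seq_len(n_frames), times = ev)
  agg <- rowsum(sz, frame_of)
  counts[as.integer(rownames(agg))] <- as.integer(agg)
  counts
}

#' Generate per-neuron spike trains
#'
#' Pre-stimulation frames are independent Bernoulli single spikes at
#' `spontaneous_fire_prob` for every neuron. Post-stimulation frames follow
#' each neuron's activity pattern (see [pattern_schedule()]): within each
#' schedule block, firing events arrive at `Poisson(rate_hz / fps)` per frame
#' and each event is expanded to a burst with the level's burst probability.
#' Unresponsive neurons keep spontaneous statistics throughout.
#'
#' @param neurons a `neuron_spec` data.frame from [sample_neurons()].
#' @param config a [sim_config()].
#' @return integer matrix of spike counts, `n_neurons` x
#'   `(n_pre_frames + n_post_frames)`.
#' @export
generate_spike_trains <- function(neurons, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(neurons)
  T_pre <- config$n_pre_frames
  T_post <- config$n_post_frames
  pp <- config$pattern_params
  spikes <- matrix(0L, n, T_pre + T_post)
  for (i in seq_len(n)) {
    spikes[i, seq_len(T_pre)] <-
      rbinom(T_pre, 1L, config$spontaneous_fire_prob)
    sched <- pattern_schedule(neurons$pattern[i], T_post)
    post <- integer(T_post)
    runs <- rle(sched)
    at <- 0L
    for (j in seq_along(runs$lengths)) {
      len <- runs$lengths[j]
      lev <- runs$values[j]
      post[at + seq_len(len)] <- if (lev == "spontaneous") {
        rbinom(len, 1L, config$spontaneous_fire_prob)
      } else {
        draw_level_spikes(len, pp[pp$level == lev, , drop = FALSE], config$fps)
      }
      at <- at + len
    }
    spikes[i, T_pre + seq_len(T_post)] <- post
  }
  rownames(spikes) <- neurons$id
  spikes
}

#' Point-spread footprint of a source at depth z
#'
#' Pixel irradiance from an isotropic point source at lateral offset d pixels
#' and depth z pixels above a planar detector is proportional to
#' `z / (d^2 + z^2)^(3/2)` (inverse square law with obliquity), truncated at
#' radius `psf_radius_factor * z`. The peak (d = 0) value is
#' `amplitude / z^2`, so deeper sources are both dimmer and wider.
#' @noRd
psf_image <- function(x_px, y_px, z_px, config) {
  H <- config$height_px
  W <- config$width_px
  dr2 <- (seq_len(H) - (y_px + 1))^2
  dc2 <- (seq_len(W) - (x_px + 1))^2
  d2 <- outer(dr2, dc2, `+`)
  v <- config$spike_amplitude * z_px / (d2 + z_px^2)^1.5
  v[d2 > (config$psf_radius_factor * z_px)^2] <- 0
  v
}

#' Render a spike matrix into sensor frames
#'
#' Each neuron's spike train is convolved with a causal calcium kernel
#' (instantaneous rise, exponential decay with time constant `decay_tau_s`,
#' truncated at five time constants) and spread onto the sensor through the
#' depth-dependent point-source footprint. Frames are the sum of a constant
#' baseline offset, a static linear illumination gradient along the long
#' axis, all neuron contributions, and additive Gaussian noise; negative
#' intensities are clipped to zero.
#'
#' @param spikes integer matrix from [generate_spike_trains()].
#' @param neurons matching `neuron_spec` data.frame.
#' @param config a [sim_config()].
#' @return numeric array `height_px` x `width_px` x `T` of detector
#'   intensities, with attributes `fps` and `n_pre_frames`.
#' @export
render_frames <- function(spikes, neurons, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(neurons)
  if (n != nrow(spikes)) stopf("'spikes' and 'neurons' disagree on neuron count")
  H <- config$height_px
  W <- config$width_px
  P <- H * W
  T_total <- ncol(spikes)

  base <- config$baseline_offset +
    config$gradient_amplitude * (seq_len(H) - 1) / max(H - 1, 1)
  M <- matrix(rep(base, W * T_total), nrow = P)  # baseline + gradient, P x T

  if (n > 0L && any(spikes > 0L)) {
    a <- exp(-1 / (config$decay_tau_s * config$fps))
    L <- ceiling(5 * config$decay_tau_s * config$fps)
    kern <- a^(0:L)
    traces <- matrix(0, n, T_total)
    for (i in seq_len(n)) {
      padded <- stats::filter(c(rep(0, L), spikes[i, ]), kern, sides = 1)
      traces[i, ] <- as.numeric(padded[L + seq_len(T_total)])
    }
    psf <- matrix(0, P, n)
    for (i in seq_len(n)) {
      psf[, i] <- psf_image(neurons$x_px[i], neurons$y_px[i],
                            neurons$z_px[i], config)
    }
    M <- M + psf %*% traces
  }
  if (config$background_noise_sd > 0) {
    # shared stray-light fluctuation: AR(1), stationary sd background_noise_sd
    ab <- exp(-1 / (config$background_tau_s * config$fps))
    innov <- rnorm(T_total, 0, config$background_noise_sd * sqrt(1 - ab^2))
    b <- as.numeric(stats::filter(innov, ab, method = "recursive"))
    M <- M + rep(b, each = P)
  }
  if (config$noise_sd > 0) {
    M <- M + rnorm(length(M), 0, config$noise_sd)
  }
  M[M < 0] <- 0
  dim(M) <- c(H, W, T_total)
  attr(M, "fps") <- config$fps
  attr(M, "n_pre_frames") <- config$n_pre_frames
  M
}

#' Simulate a complete lensless calcium imaging dataset
#'
#' Composes [sample_neurons()], [generate_spike_trains()] and
#' [render_frames()] under the configuration seed, returning the rendered
#' frames together with the full ground truth. Two calls with the same seeded
#' config produce bit-identical datasets.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_dataset`: list with `frames`
#'   (H x W x T array), `neurons`, `spikes`, `config`, `seed`.
#' @examples
#' cfg <- sim_config(n_pre_frames = 50, n_post_frames = 100, n_neurons = 5,
#'                   seed = 1)
#' ds <- simulate_dataset(cfg)
#' dim(ds$frames)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    neurons <- sample_neurons(config)
    spikes <- generate_spike_trains(neurons, config)
    frames <- render_frames(spikes, neurons, config)
    structure(list(frames = frames, neurons = neurons, spikes = spikes,
                   config = config, seed = config$seed),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Simulated lensless Ca2+ dataset: %d x %d px, %d frames (%d pre + %d post)\n",
              d[1], d[2], d[3], x$config$n_pre_frames, x$config$n_post_frames))
  if (nrow(x$neurons)) {
    cat(sprintf("  %d neurons: %s\n", nrow(x$neurons),
                paste(sprintf("%s=%d", names(table(x$neurons$pattern)),
                              as.integer(table(x$neurons$pattern))),
                      collapse = ", ")))
  }
  cat(sprintf("  seed: %s\n", x$seed %||% "NULL"))
  invisible(x)
}

#' @export
plot.sim_dataset <- function(x, ...) {
  avg <- apply(x$frames, c(1, 2), mean)
  image(t(avg)[, nrow(avg):1], col = gray(seq(0, 1, length.out = 256)),
        axes = FALSE, main = "Mean frame with ground-truth neurons", ...)
  if (nrow(x$neurons)) {
    H <- nrow(avg); W <- ncol(avg)
    pat <- factor(x$neurons$pattern,
                  levels = c("pattern1", "pattern2", "unresponsive"))
    points((x$neurons$x_px + 0.5) / W, 1 - (x$neurons$y_px + 0.5) / H,
           col = c("blue", "orange", "black")[as.integer(pat)], pch = 19)
    legend("topright", legend = levels(pat),
           col = c("blue", "orange", "black"), pch = 19, cex = 0.7, bg = "white")
  }
  invisible(x)
}
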