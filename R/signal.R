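#' STFT parameters
#'
#' Window, segment length and overlap used by [spectral_subtract()]. The
#' defaults (periodic Hann window, 256-frame segments, 50\% overlap) satisfy
#' the constant-overlap-add condition, so the transform is perfectly
#' invertible, and at 10 fps resolve spectral structure well below 0.05 Hz.
#'
#' @param window window type; only `"hann"` is implemented.
#' @param nperseg segment length in frames.
#' @param noverlap overlap between consecutive segments in frames
#'   (default `nperseg / 2`).
#' @return object of class `stft_params`.
#' @export
stft_params <- function(window = "hann", nperseg = 256L, noverlap = NULL) {
  window <- match.arg(window, "hann")
  check_scalar_number(nperseg, "nperseg", 2, Inf, integer = TRUE)
  noverlap <- noverlap %||% (nperseg %/% 2L)
  check_scalar_number(noverlap, "noverlap", 0, nperseg - 1L, integer = TRUE)
  structure(list(window = window, nperseg = as.integer(nperseg),
                 noverlap = as.integer(noverlap)),
            class = "stft_params")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq.int(0L, n - 1L) / n)

#' Short-time Fourier transform
#'
#' Windows the signal into overlapping segments and returns the full complex
#' spectrum of each. The signal is zero-padded by half a segment on both
#' sides (and at the tail up to a whole hop) so that every sample receives
#' full window coverage and [istft()] can reconstruct it exactly.
#'
#' @param x numeric vector.
#' @param params an [stft_params()].
#' @return object of class `stft`: list with the complex `nperseg` x
#'   `n_segments` matrix `S`, `params` and the original length `n`.
#' @export
stft <- function(x, params = stft_params()) {
  stopifnot(inherits(params, "stft_params"))
  n <- length(x)
  np <- params$nperseg
  if (n < np) stopf("signal of length %d shorter than one %d-frame segment", n, np)
  hop <- np - params$noverlap
  pad <- np %/% 2L
  xp <- c(numeric(pad), x, numeric(pad))
  n_seg <- ceiling((length(xp) - np) / hop) + 1L
  xp <- c(xp, numeric((n_seg - 1L) * hop + np - length(xp)))
  w <- hann_window(np)
  S <- matrix(0i, np, n_seg)
  for (k in seq_len(n_seg)) {
    seg <- xp[(k - 1L) * hop + seq_len(np)]
    S[, k] <- fft(w * seg)
  }
  structure(list(S = S, params = params, n = n), class = "stft")
}

#' Inverse short-time Fourier transform
#'
#' Weighted overlap-add reconstruction: each segment spectrum is inverted,
#' multiplied by the synthesis (= analysis) window, accumulated, and
#' normalized by the summed squared window. Returns a signal of the original
#' length.
#'
#' @param s an `stft` object (possibly with a modified spectrum matrix `S`).
#' @return numeric vector of length `s$n`.
#' @export
istft <- function(s) {
  stopifnot(inherits(s, "stft"))
  np <- s$params$nperseg
  hop <- np - s$params$noverlap
  n_seg <- ncol(s$S)
  total <- (n_seg - 1L) * hop + np
  w <- hann_window(np)
  y <- numeric(total)
  den <- numeric(total)
  for (k in seq_len(n_seg)) {
    seg <- Re(fft(s$S[, k], inverse = TRUE)) / np
    rng <- (k - 1L) * hop + seq_len(np)
    y[rng] <- y[rng] + w * seg
    den[rng] <- den[rng] + w^2
  }
  good <- den > .Machine$double.eps
  y[good] <- y[good] / den[good]
  pad <- np %/% 2L
  y[pad + seq_len(s$n)]
}

#' Background (non-ROI) noise reference trace
#'
#' The lensless sensor picks up non-stationary stray light in every pixel;
#' pixels outside all ROIs carry mostly that noise. This returns the
#' per-frame mean percent dF/F over all background pixels, for use as the
#' noise reference in [spectral_subtract()].
#'
#' @param dff H x W x T percent dF/F array.
#' @param mask a `roi_mask` or binary matrix; 1 marks ROI pixels.
#' @return numeric vector of length T.
#' @export
noise_trace <- function(dff, mask) {
  dff <- as_stack(dff, "dff")
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  check_binary(m, "mask")
  if (!all(dim(m) == dim(dff)[1:2])) stopf("mask and stack shapes disagree")
  bg <- which(m == 0)
  if (length(bg) == 0L) stopf("mask covers the whole frame; no background pixels")
  d <- dim(dff)
  colMeans(matrix(dff, d[1L] * d[2L], d[3L])[bg, , drop = FALSE])
}

#' STFT spectral subtraction
#'
#' Denoises an ROI trace against a noise reference: the noise magnitude
#' spectrogram is subtracted from the trace's magnitude spectrogram (negative
#' results floored at zero, the standard spectral-subtraction rule), the
#' trace's phase is kept, and the inverse STFT returns a trace of the
#' original length.
#'
#' @param trace numeric ROI trace.
#' @param noise noise reference of the same length (see [noise_trace()]).
#' @param params an [stft_params()].
#' @return denoised numeric vector, same length as `trace`.
#' @export
spectral_subtract <- function(trace, noise, params = stft_params()) {
  if (length(trace) != length(noise)) {
    stopf("'trace' (%d) and 'noise' (%d) lengths differ",
          length(trace), length(noise))
  }
  st <- stft(trace, params)
  sn <- stft(noise, params)
  mag <- pmax(Mod(st$S) - Mod(sn$S), 0)
  st$S <- mag * exp(1i * Arg(st$S))
  istft(st)
}
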