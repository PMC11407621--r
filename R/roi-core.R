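#' Per-pixel percent dF/F baselining
#'
#' Converts raw fluorescence to percent change over baseline:
#' `100 * (F[i, t] - F0[i]) / F0[i]`, where `F0[i]` is the mean of pixel i
#' over the first `n_baseline_frames` frames. Pixels whose baseline mean is
#' zero are mapped to 0 for all frames (with a warning), so the output is
#' finite everywhere.
#'
#' @param stack H x W x T numeric array of raw fluorescence.
#' @param n_baseline_frames number of leading frames forming the baseline.
#' @return H x W x T array of percent dF/F, with attribute
#'   `baseline_frames`.
#' @export
compute_dff <- function(stack, n_baseline_frames) {
  stack <- as_stack(stack)
  d <- dim(stack)
  check_scalar_number(n_baseline_frames, "n_baseline_frames", 1, d[3L],
                      integer = TRUE)
  P <- d[1L] * d[2L]
  M <- matrix(stack, P, d[3L])
  F0 <- rowMeans(M[, seq_len(n_baseline_frames), drop = FALSE])
  zero <- F0 == 0
  if (any(zero)) {
    warning(sprintf("%d pixel(s) with zero baseline mapped to 0", sum(zero)))
    F0[zero] <- 1  # placeholder; rows reset below
  }
  dff <- 100 * (M - F0) / F0
  if (any(zero)) dff[zero, ] <- 0
  dim(dff) <- d
  attr(dff, "baseline_frames") <- as.integer(n_baseline_frames)
  dff
}

#' Gaussian adaptive (local) binarization
#'
#' Thresholds each pixel against the Gaussian-weighted mean of its
#' `block_size` x `block_size` neighborhood (kernel standard deviation
#' `sigma`, truncated to the block, boundaries reflected). A pixel is
#' foreground only if it strictly exceeds its local threshold, so constant
#' regions binarize to zero.
#'
#' @param image numeric matrix.
#' @param sigma Gaussian kernel standard deviation in pixels (> 0).
#' @param block_size odd neighborhood side length (>= 3).
#' @return binary matrix (0/1) of the same shape.
#' @export
adaptive_binarize <- function(image, sigma, block_size = 15L) {
  if (!is.matrix(image) || !all(is.finite(image))) {
    stopf("'image' must be a finite numeric matrix")
  }
  check_scalar_number(sigma, "sigma", lower = 1e-12)
  check_block_size(block_size, dim(image))
  g <- gauss_kernel1d(sigma, block_size)
  thr <- sep_filter_image(image, band_reflect(nrow(image), g),
                          band_reflect(ncol(image), g))
  (image > thr + tie_eps(image)) + 0
}

# tolerance shielding the strict > comparison from floating-point ties
# (a constant region must binarize to exactly zero)
tie_eps <- function(x) 1e-9 * max(1, abs(range(x)))

check_block_size <- function(block_size, dims) {
  check_scalar_number(block_size, "block_size", 3, Inf, integer = TRUE)
  if (block_size %% 2L == 0L) stopf("'block_size' must be odd")
  if (block_size > 2L * min(dims) - 1L) {
    stopf("'block_size' = %d too large for a %d x %d image",
          block_size, dims[1L], dims[2L])
  }
  invisible(block_size)
}

#' Morphological opening with a square footprint
#'
#' Erosion followed by dilation. Erosion keeps a pixel only if every pixel
#' under the square footprint is foreground (the image is zero-padded, so
#' features touching the border erode); dilation then sets a pixel if any
#' pixel under the reflected footprint is foreground. Features smaller than
#' the footprint are removed. Odd footprints are centered; even ones anchor
#' at the floor-center pixel.
#'
#' @param binary binary matrix (0/1).
#' @param footprint_side integer side length of the square footprint (>= 1).
#' @return binary matrix of the same shape.
#' @export
morphological_opening <- function(binary, footprint_side) {
  if (!is.matrix(binary)) stopf("'binary' must be a matrix")
  check_binary(binary, "binary")
  check_scalar_number(footprint_side, "footprint_side", 1, Inf, integer = TRUE)
  if (footprint_side == 1L) return(binary + 0)
  offs <- footprint_offsets(footprint_side)
  Bye <- band_zero(nrow(binary), offs)
  Bxe <- band_zero(ncol(binary), offs)
  er <- (sep_filter_image(binary, Bye, Bxe) >= footprint_side^2 - 1e-9) + 0
  # dilation by the reflected footprint (adjoint of the erosion)
  Byd <- band_zero(nrow(binary), -offs)
  Bxd <- band_zero(ncol(binary), -offs)
  (sep_filter_image(er, Byd, Bxd) > 1e-9) + 0
}

#' Morphological area opening
#'
#' Removes connected components whose pixel count is strictly below
#' `min_area`; components of exactly `min_area` pixels are retained.
#'
#' @param binary binary matrix (0/1).
#' @param min_area minimum component area in pixels (>= 0).
#' @param connectivity 8 (default) or 4.
#' @return binary matrix of the same shape.
#' @export
area_opening <- function(binary, min_area, connectivity = 8) {
  if (!is.matrix(binary)) stopf("'binary' must be a matrix")
  check_binary(binary, "binary")
  check_scalar_number(min_area, "min_area", lower = 0)
  if (!connectivity %in% c(4, 8)) stopf("'connectivity' must be 4 or 8")
  if (min_area <= 0) return(binary + 0)
  lab <- label_components(binary, connectivity)
  k <- max(lab)
  if (k == 0L) return(binary + 0)
  sizes <- tabulate(lab[lab > 0L], nbins = k)
  out <- binary + 0
  small <- which(sizes < min_area)
  if (length(small)) out[lab %in% small] <- 0
  out
}

#' Average a set of binary frames
#'
#' @param binary_frames list of equal-shape binary matrices, or a binary
#'   H x W x T array.
#' @return numeric matrix of per-pixel means, values in \[0, 1\].
#' @export
average_binary <- function(binary_frames) {
  if (is.list(binary_frames)) {
    if (length(binary_frames) == 0L) stopf("'binary_frames' is empty")
    dims <- dim(binary_frames[[1L]])
    binary_frames <- array(unlist(binary_frames),
                           c(dims, length(binary_frames)))
  }
  arr <- as_stack(binary_frames, "binary_frames")
  check_binary(arr, "binary_frames")
  d <- dim(arr)
  matrix(rowMeans(matrix(arr, d[1L] * d[2L], d[3L])), d[1L], d[2L])
}

#' Parameters of the ROI determination algorithm
#'
#' The seven tunables of the two-pass pipeline plus the adaptive-threshold
#' block size: sigma, opening footprint and minimum area for the per-frame
#' pass (`sigma1`, `fp1`, `area1`) and for the second pass on the averaged
#' image (`sigma2`, `fp2`, `area2`), and `time_frames`, the number of frames
#' entering the per-frame stage (NULL = all frames of the analyzed segment).
#' Defaults are the optimized settings (sigma = 1.5, footprint 3, areas 0)
#' that give uniformly distributed, consistently sized ROIs. `block_size`
#' is kept out of the tunable set because it was found not to affect ROI
#' selection.
#'
#' @param sigma1,sigma2 Gaussian kernel standard deviations, pixels (> 0).
#' @param fp1,fp2 square opening footprint side lengths, pixels (>= 1).
#' @param area1,area2 minimum connected-component areas, pixels (>= 0).
#' @param time_frames frames entering the per-frame stage, or NULL for all.
#' @param block_size odd adaptive-threshold window side (>= 3).
#' @return object of class `algorithm_params`.
#' @export
algorithm_params <- function(sigma1 = 1.5, fp1 = 3L, area1 = 0,
                             sigma2 = 1.5, fp2 = 3L, area2 = 0,
                             time_frames = NULL, block_size = 15L) {
  check_scalar_number(sigma1, "sigma1", lower = 1e-12)
  check_scalar_number(sigma2, "sigma2", lower = 1e-12)
  check_scalar_number(fp1, "fp1", 1, Inf, integer = TRUE)
  check_scalar_number(fp2, "fp2", 1, Inf, integer = TRUE)
  check_scalar_number(area1, "area1", lower = 0)
  check_scalar_number(area2, "area2", lower = 0)
  if (!is.null(time_frames)) {
    check_scalar_number(time_frames, "time_frames", 1, Inf, integer = TRUE)
  }
  check_scalar_number(block_size, "block_size", 3, Inf, integer = TRUE)
  if (block_size %% 2L == 0L) stopf("'block_size' must be odd")
  structure(list(sigma1 = sigma1, fp1 = as.integer(fp1), area1 = area1,
                 sigma2 = sigma2, fp2 = as.integer(fp2), area2 = area2,
                 time_frames = if (is.null(time_frames)) NULL
                               else as.integer(time_frames),
                 block_size = as.integer(block_size)),
            class = "algorithm_params")
}

#' @export
print.algorithm_params <- function(x, ...) {
  cat(sprintf(
    "ROI algorithm parameters: sigma1=%g fp1=%d area1=%g | sigma2=%g fp2=%d area2=%g | time=%s block=%d\n",
    x$sigma1, x$fp1, x$area1, x$sigma2, x$fp2, x$area2,
    if (is.null(x$time_frames)) "all" else x$time_frames, x$block_size))
  invisible(x)
}

# one cleaned-binary pass over a chunk of frames, returning the per-pixel
# sum of the cleaned frames (steps 1-3 of the pipeline, batched)
clean_chunk_sum <- function(sub, params, Ky, Kx, Bye, Bxe, Byd, Bxd) {
  d <- dim(sub)
  thr <- sep_filter_stack(sub, Ky, Kx)
  bin <- (sub > thr + tie_eps(sub)) + 0
  if (params$fp1 > 1L) {
    er <- (sep_filter_stack(bin, Bye, Bxe) >= params$fp1^2 - 1e-9) + 0
    bin <- (sep_filter_stack(er, Byd, Bxd) > 1e-9) + 0
  }
  if (params$area1 > 0) {
    for (t in seq_len(d[3L])) {
      bin[, , t] <- area_opening(bin[, , t, drop = TRUE], params$area1)
    }
  }
  rowSums(matrix(bin, d[1L] * d[2L], d[3L]))
}

#' Determine ROIs from a dF/F stack
#'
#' Runs the two-pass ROI determination pipeline. Pass 1, applied to each of
#' the first `time_frames` frames: Gaussian adaptive binarization (`sigma1`),
#' morphological opening (`fp1`), area opening (`area1`). The cleaned binary
#' frames are averaged into a real-valued occupancy image. Pass 2, applied
#' once to that average: adaptive binarization (`sigma2`), opening (`fp2`),
#' area opening (`area2`). The result is the final ROI mask; pixels that are
#' consistently local maxima of the dF/F video survive both passes.
#'
#' @param dff H x W x T array of percent dF/F frames (see [compute_dff()]).
#' @param params an [algorithm_params()].
#' @return object of class `roi_mask`: list with the binary `mask`, the
#'   real-valued `average_image`, `n_roi`, `mean_roi_area` (foreground
#'   pixels / component count), `params` and `time_frames`.
#' @export
determine_rois <- function(dff, params = algorithm_params()) {
  dff <- as_stack(dff, "dff")
  stopifnot(inherits(params, "algorithm_params"))
  d <- dim(dff)
  tf <- params$time_frames %||% d[3L]
  if (tf < 1L || tf > d[3L]) {
    stopf("'time_frames' = %d outside the stack's %d frames", tf, d[3L])
  }
  check_block_size(params$block_size, d[1:2])

  g1 <- gauss_kernel1d(params$sigma1, params$block_size)
  Ky <- band_reflect(d[1L], g1)
  Kx <- band_reflect(d[2L], g1)
  offs <- footprint_offsets(params$fp1)
  Bye <- band_zero(d[1L], offs); Bxe <- band_zero(d[2L], offs)
  Byd <- band_zero(d[1L], -offs); Bxd <- band_zero(d[2L], -offs)

  acc <- numeric(d[1L] * d[2L])
  chunk <- 1024L
  starts <- seq.int(1L, tf, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, tf)
    acc <- acc + clean_chunk_sum(dff[, , idx, drop = FALSE], params,
                                 Ky, Kx, Bye, Bxe, Byd, Bxd)
  }
  avg <- matrix(acc / tf, d[1L], d[2L])

  mask <- adaptive_binarize(avg, params$sigma2, params$block_size)
  mask <- morphological_opening(mask, params$fp2)
  mask <- area_opening(mask, params$area2)

  lab <- label_components(mask)
  n_roi <- max(lab)
  structure(list(
    mask = mask,
    average_image = avg,
    n_roi = n_roi,
    mean_roi_area = if (n_roi > 0L) sum(mask) / n_roi else 0,
    params = params,
    time_frames = tf,
    dim = d
  ), class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI mask %d x %d: %d ROI(s), mean area %.2f px\n",
              nrow(x$mask), ncol(x$mask), x$n_roi, x$mean_roi_area))
  invisible(x)
}

#' @export
summary.roi_mask <- function(object, ...) {
  rois <- label_rois(object)
  cat(sprintf("ROI mask %d x %d from %d frame(s)\n",
              nrow(object$mask), ncol(object$mask), object$time_frames))
  print(object$params)
  cat(sprintf("  %d ROI(s), %d foreground px, mean area %.2f px\n",
              object$n_roi, sum(object$mask), object$mean_roi_area))
  if (nrow(rois$table)) {
    cat("  area quartiles:",
        paste(stats::quantile(rois$table$area), collapse = " "), "\n")
  }
  invisible(rois$table)
}

#' @export
plot.roi_mask <- function(x, neurons = NULL, ...) {
  m <- x$mask
  image(t(m)[, nrow(m):1, drop = FALSE], col = c("black", "white"),
        axes = FALSE, main = sprintf("%d ROIs", x$n_roi), ...)
  if (!is.null(neurons) && nrow(neurons)) {
    points((neurons$x_px + 0.5) / ncol(m), 1 - (neurons$y_px + 0.5) / nrow(m),
           col = "red", pch = 4)
  }
  invisible(x)
}

#' Label the connected components of an ROI mask
#'
#' @param mask a `roi_mask` or a binary matrix.
#' @return object of class `roi_set`: list with the integer `labels` matrix
#'   (0 = background, components numbered 1..K in raster order), a `table`
#'   data.frame (`label`, `area`, `centroid_row`, `centroid_col`, 1-based),
#'   and `pixels`, a list of column-major pixel indices per ROI.
#' @export
label_rois <- function(mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!is.matrix(m)) stopf("'mask' must be a matrix or roi_mask")
  check_binary(m, "mask")
  lab <- label_components(m, 8)
  k <- max(lab)
  H <- nrow(m)
  pixels <- vector("list", k)
  tab <- data.frame(label = integer(0), area = integer(0),
                    centroid_row = numeric(0), centroid_col = numeric(0))
  if (k > 0L) {
    idx <- which(lab > 0L)
    pixels <- split(idx, lab[idx])
    rows <- (idx - 1L) %% H + 1L
    cols <- (idx - 1L) %/% H + 1L
    tab <- data.frame(
      label = seq_len(k),
      area = as.integer(lengths(pixels)),
      centroid_row = as.numeric(tapply(rows, lab[idx], mean)),
      centroid_col = as.numeric(tapply(cols, lab[idx], mean))
    )
  }
  structure(list(labels = lab, table = tab, pixels = pixels),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set: %d ROI(s)\n", nrow(x$table)))
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}

#' Percent dF/F trace of one ROI
#'
#' The ROI trace is `100 * (Fbar[t] - F0) / F0` where `Fbar[t]` is the mean
#' raw fluorescence over the ROI pixels at frame t and `F0` is the mean over
#' the ROI pixels and the baseline frames.
#'
#' @param stack H x W x T raw fluorescence array.
#' @param roi integer vector of column-major pixel indices (e.g. one element
#'   of a [label_rois()] `pixels` list).
#' @param n_baseline_frames number of leading baseline frames.
#' @return numeric vector of length T, percent dF/F.
#' @export
roi_trace <- function(stack, roi, n_baseline_frames) {
  stack <- as_stack(stack)
  d <- dim(stack)
  check_scalar_number(n_baseline_frames, "n_baseline_frames", 1, d[3L],
                      integer = TRUE)
  roi <- as.integer(roi)
  if (length(roi) == 0L) stopf("'roi' is empty")
  if (any(roi < 1L | roi > d[1L] * d[2L])) stopf("'roi' indices out of range")
  M <- matrix(stack, d[1L] * d[2L], d[3L])
  fbar <- colMeans(M[roi, , drop = FALSE])
  f0 <- mean(fbar[seq_len(n_baseline_frames)])
  if (f0 == 0) stopf("ROI baseline fluorescence is zero")
  100 * (fbar - f0) / f0
}

#' Percent dF/F traces for every ROI in a set
#'
#' @param stack H x W x T raw fluorescence array.
#' @param rois a `roi_set` from [label_rois()].
#' @param n_baseline_frames number of leading baseline frames.
#' @return T x K matrix, one column per ROI, colnames = ROI labels.
#' @export
roi_traces <- function(stack, rois, n_baseline_frames) {
  stopifnot(inherits(rois, "roi_set"))
  stack <- as_stack(stack)
  d <- dim(stack)
  check_scalar_number(n_baseline_frames, "n_baseline_frames", 1, d[3L],
                      integer = TRUE)
  M <- matrix(stack, d[1L] * d[2L], d[3L])
  k <- length(rois$pixels)
  out <- matrix(0, d[3L], k)
  for (j in seq_len(k)) {
    fbar <- colMeans(M[rois$pixels[[j]], , drop = FALSE])
    f0 <- mean(fbar[seq_len(n_baseline_frames)])
    if (f0 == 0) stopf("ROI %d has zero baseline fluorescence", j)
    out[, j] <- 100 * (fbar - f0) / f0
  }
  colnames(out) <- rois$table$label
  out
}
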