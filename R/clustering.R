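#' Reduce ROI traces to principal component scores
#'
#' Projects traces (one row per ROI) onto the smallest set of leading
#' principal components whose cumulative explained variance reaches
#' `variance_threshold`. Using the full-trace principal components, rather
#' than a hand-picked time window, avoids biasing the subsequent clustering
#' to the minutes where activity differences are most obvious.
#'
#' @param traces K x T numeric matrix, one row per ROI.
#' @param variance_threshold fraction of variance to retain, in (0, 1\].
#' @return object of class `trace_scores`: list with the K x m `scores`
#'   matrix, `n_components`, and the cumulative `variance_explained` profile.
#' @export
reduce_traces <- function(traces, variance_threshold = 0.95) {
  if (!is.matrix(traces) || nrow(traces) < 2L) {
    stopf("'traces' must be a matrix with at least 2 rows (ROIs)")
  }
  check_scalar_number(variance_threshold, "variance_threshold", 1e-9, 1)
  p <- prcomp(traces, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  if (sum(v) <= 0) stopf("traces have zero variance")
  cum <- cumsum(v) / sum(v)
  m <- which(cum >= variance_threshold - 1e-12)[1L]
  structure(list(
    scores = p$x[, seq_len(m), drop = FALSE],
    n_components = m,
    variance_explained = cum
  ), class = "trace_scores")
}

#' Cluster ROI activity by k-means with silhouette model selection
#'
#' Runs k-means (multiple restarts) for each candidate number of clusters
#' and keeps the k with the highest mean silhouette width; ties go to the
#' smallest k. Identical duplicated inputs (fewer distinct points than
#' `k_min + 1`) are a degenerate case and raise an error.
#'
#' @param scores a `trace_scores` object or a numeric score matrix
#'   (rows = ROIs).
#' @param k_min,k_max candidate range for the number of clusters.
#' @param nstart k-means restarts per candidate k.
#' @param seed integer seed for the restarts (reproducible labels).
#' @param traces optional K x T trace matrix used to attach per-cluster mean
#'   traces to the result.
#' @return object of class `cluster_result`: `labels` (1..k per ROI), `k`,
#'   `silhouette` (named mean silhouette per candidate k), `n_components`,
#'   and `cluster_means` (k x T, if `traces` given).
#' @export
cluster_traces <- function(scores, k_min = 2L, k_max = 10L, nstart = 10L,
                           seed = NULL, traces = NULL) {
  X <- if (inherits(scores, "trace_scores")) scores$scores else scores
  if (!is.matrix(X)) stopf("'scores' must be a matrix or trace_scores")
  check_scalar_number(k_min, "k_min", 2, Inf, integer = TRUE)
  check_scalar_number(k_max, "k_max", k_min, Inf, integer = TRUE)
  n <- nrow(X)
  n_distinct <- nrow(unique(X))
  if (n_distinct < k_min + 1L) {
    stopf("only %d distinct point(s); need at least k_min + 1 = %d",
          n_distinct, k_min + 1L)
  }
  k_hi <- min(k_max, n_distinct - 1L, n - 1L)
  dd <- dist(X)
  ks <- seq.int(k_min, k_hi)
  sil <- setNames(numeric(length(ks)), ks)
  fits <- vector("list", length(ks))
  with_seed(seed, {
    for (i in seq_along(ks)) {
      km <- kmeans(X, centers = ks[i], nstart = nstart, iter.max = 100L)
      sw <- cluster::silhouette(km$cluster, dd)
      sil[i] <- mean(sw[, "sil_width"])
      fits[[i]] <- km
    }
  })
  best <- which(sil >= max(sil) - 1e-12)[1L]  # ties -> smallest k
  km <- fits[[best]]
  res <- structure(list(
    labels = km$cluster,
    k = ks[best],
    silhouette = sil,
    centers = km$centers,
    n_components = if (inherits(scores, "trace_scores"))
      scores$n_components else ncol(X),
    cluster_means = NULL
  ), class = "cluster_result")
  if (!is.null(traces)) {
    if (nrow(traces) != n) stopf("'traces' rows must match 'scores' rows")
    res$cluster_means <- rowsum(traces, km$cluster) /
      as.vector(table(km$cluster))
  }
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("Activity clustering: k = %d (mean silhouette %.3f), %d PC(s)\n",
              x$k, x$silhouette[as.character(x$k)], x$n_components))
  cat("  cluster sizes:", paste(as.integer(table(x$labels)), collapse = ", "),
      "\n")
  cat("  silhouette by k:",
      paste(sprintf("%s:%.3f", names(x$silhouette), x$silhouette),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
plot.cluster_result <- function(x, ...) {
  if (!is.null(x$cluster_means)) {
    op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(par(op))
    matplot(t(x$cluster_means), type = "l", lty = 1,
            xlab = "frame", ylab = "mean trace",
            main = sprintf("Per-cluster mean traces (k = %d)", x$k), ...)
    legend("topright", legend = rownames(x$cluster_means),
           col = seq_len(x$k), lty = 1, cex = 0.7)
  }
  plot(as.integer(names(x$silhouette)), x$silhouette, type = "b",
       xlab = "k", ylab = "mean silhouette", main = "Silhouette model selection")
  abline(v = x$k, lty = 2)
  invisible(x)
}

#' Identify the active cluster
#'
#' Returns the cluster whose member traces have the highest time-averaged
#' mean over the given frame window (by convention the post-stimulation
#' window); ties go to the smallest cluster label.
#'
#' @param result a `cluster_result`.
#' @param traces K x T trace matrix the clustering was computed from.
#' @param frames optional integer vector of frame (column) indices to
#'   average over; default all.
#' @return integer cluster id.
#' @export
active_cluster <- function(result, traces, frames = NULL) {
  stopifnot(inherits(result, "cluster_result"))
  if (nrow(traces) != length(result$labels)) {
    stopf("'traces' rows must match the clustered ROIs")
  }
  frames <- frames %||% seq_len(ncol(traces))
  lvl <- sort(unique(result$labels))
  per_roi <- rowMeans(traces[, frames, drop = FALSE])
  cl_mean <- vapply(lvl, function(l) mean(per_roi[result$labels == l]),
                    numeric(1))
  lvl[which.max(cl_mean)]  # which.max takes the first (smallest label) on ties
}

#' Full ROI-trace clustering pipeline
#'
#' Convenience wrapper preparing clustering features from (typically
#' spectrally subtracted, post-stimulation) ROI traces, then reducing with
#' PCA at the given variance threshold and clustering with
#' silhouette-selected k-means.
#'
#' Feature preparation: traces are averaged into `bin_frames`-frame bins
#' (suppressing frame-rate noise), centered, and divided by a noise-floor
#' regularized scale `sqrt(sd_i^2 + (noise_floor * median(sd))^2)`. The
#' regularization normalizes away the large amplitude differences between
#' shallow and deep neurons, which would otherwise dominate the Euclidean
#' geometry, while leaving near-silent traces small: a plain per-trace
#' z-score would blow pure-noise ROI traces up to unit variance and
#' manufacture spurious clusters out of them.
#'
#' @inheritParams cluster_traces
#' @param traces K x T matrix of ROI traces (rows = ROIs).
#' @param variance_threshold passed to [reduce_traces()].
#' @param bin_frames temporal bin width in frames (6 s at 10 fps by
#'   default); capped at the trace length.
#' @param noise_floor noise-floor multiple of the median trace standard
#'   deviation used in the scale regularization.
#' @return a `cluster_result`; the `kept` attribute gives the trace rows
#'   that survived the degenerate-trace filter.
#' @export
cluster_roi_traces <- function(traces, variance_threshold = 0.95,
                               k_min = 2L, k_max = 10L, nstart = 10L,
                               seed = NULL, bin_frames = 60L,
                               noise_floor = 2) {
  if (!is.matrix(traces)) stopf("'traces' must be a matrix")
  check_scalar_number(bin_frames, "bin_frames", 1, Inf, integer = TRUE)
  check_scalar_number(noise_floor, "noise_floor", lower = 0)
  T_len <- ncol(traces)
  K <- nrow(traces)
  bin <- min(bin_frames, T_len)
  nb <- T_len %/% bin
  S <- t(colMeans(array(t(traces[, seq_len(nb * bin), drop = FALSE]),
                        c(bin, nb, K))))
  sds <- apply(S, 1L, sd)
  scale <- sqrt(sds^2 + (noise_floor * stats::median(sds))^2)
  keep <- which(scale > 0)
  if (length(keep) < K) {
    warning(sprintf("dropping %d degenerate trace(s) before PCA",
                    K - length(keep)))
  }
  feats <- (S[keep, , drop = FALSE] - rowMeans(S[keep, , drop = FALSE])) /
    scale[keep]
  scores <- reduce_traces(feats, variance_threshold)
  res <- cluster_traces(scores, k_min = k_min, k_max = k_max, nstart = nstart,
                        seed = seed, traces = traces[keep, , drop = FALSE])
  attr(res, "kept") <- keep
  res
}
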