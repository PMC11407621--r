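# Small simulation configurations used across test files.

tiny_config <- function(seed = 1L, ...) {
  sim_config(height_px = 60L, width_px = 24L,
             n_pre_frames = 100L, n_post_frames = 300L,
             n_neurons = 6L,
             x_range = c(5L, 18L), y_range = c(5L, 54L),
             seed = seed, ...)
}

# the reduced-frame study conditions used by the acceptance checks:
# the full design scaled to 1/20 of the frame count (450 pre + 1800 post),
# all other parameters at their defaults
study_config <- function(seed = 1L, ...) {
  sim_config(n_pre_frames = 450L, n_post_frames = 1800L, seed = seed, ...)
}

# shared cache so expensive acceptance computations run once per session
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (is.null(.acceptance_cache$study)) {
    .acceptance_cache$study <- replicate_study(
      study_config(seed = 1L), algorithm_params(), n_replicates = 100L
    )
  }
  .acceptance_cache$study
}

# one full detect -> traces -> denoise -> cluster run; returns chosen k and
# the ARI between cluster labels and ground-truth patterns of neuron-bearing
# ROIs
cluster_run <- function(seed) {
  cfg <- study_config(seed = seed)
  ds <- simulate_dataset(cfg)
  dff <- compute_dff(ds$frames, cfg$n_pre_frames)
  post_idx <- cfg$n_pre_frames + seq_len(cfg$n_post_frames)
  rois <- determine_rois(dff[, , post_idx, drop = FALSE], algorithm_params())
  rset <- label_rois(rois)
  traces <- roi_traces(ds$frames, rset, cfg$n_pre_frames)
  noise <- noise_trace(dff, rois)
  tss <- apply(traces, 2, spectral_subtract, noise = noise)
  cl <- cluster_roi_traces(t(tss[post_idx, , drop = FALSE]), seed = seed)
  gt <- rep(NA_character_, nrow(rset$table))
  roi_of <- rset$labels[cbind(ds$neurons$y_px + 1L, ds$neurons$x_px + 1L)]
  for (i in seq_len(nrow(ds$neurons))) {
    if (roi_of[i] > 0L) gt[roi_of[i]] <- ds$neurons$pattern[i]
  }
  has <- !is.na(gt)
  kept <- attr(cl, "kept")
  has_k <- has[kept]
  ari <- if (requireNamespace("mclust", quietly = TRUE) && sum(has_k) >= 2) {
    mclust::adjustedRandIndex(cl$labels[has_k], gt[kept][has_k])
  } else {
    NA_real_
  }
  list(k = cl$k, ari = ari)
}

acceptance_cluster_runs <- function() {
  if (is.null(.acceptance_cache$cluster_runs)) {
    .acceptance_cache$cluster_runs <- lapply(1:10, cluster_run)
  }
  .acceptance_cache$cluster_runs
}
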