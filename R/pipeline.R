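#' End-to-end pipeline configuration
#'
#' @param input path to the input stack (TIFF or RDS), or NULL when a stack
#'   is passed to [run_pipeline()] directly.
#' @param baseline_frames number of leading pre-stimulation frames used as
#'   the dF/F baseline; the remaining frames are the analyzed
#'   (post-stimulation) segment. The convention follows the recording
#'   protocol of ~15 minutes of baseline before stimulation.
#' @param params an [algorithm_params()].
#' @param stft an [stft_params()].
#' @param variance_threshold PCA variance fraction for clustering.
#' @param k_min,k_max,nstart k-means settings, see [cluster_traces()].
#' @param out_dir output directory.
#' @param seed integer seed driving the clustering restarts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, baseline_frames,
                            params = algorithm_params(),
                            stft = stft_params(),
                            variance_threshold = 0.95,
                            k_min = 2L, k_max = 10L, nstart = 10L,
                            out_dir = ".", seed = 0L) {
  check_scalar_number(baseline_frames, "baseline_frames", 1, Inf,
                      integer = TRUE)
  stopifnot(inherits(params, "algorithm_params"),
            inherits(stft, "stft_params"))
  structure(list(input = input, baseline_frames = as.integer(baseline_frames),
                 params = params, stft = stft,
                 variance_threshold = variance_threshold,
                 k_min = as.integer(k_min), k_max = as.integer(k_max),
                 nstart = as.integer(nstart),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full ROI pipeline
#'
#' Executes the complete analysis on one recording: percent dF/F baselining,
#' two-pass ROI determination on the post-baseline frames, per-ROI trace
#' extraction, STFT spectral subtraction against the non-ROI noise
#' reference, PCA + silhouette-selected k-means clustering of the denoised
#' post-stimulation traces, and active-cluster identification. All outputs
#' (mask, ROI table, raw and denoised traces, cluster assignments,
#' per-cluster mean traces, JSON run manifest) are written to
#' `config$out_dir`.
#'
#' If the mask yields fewer than three ROIs the clustering stages are
#' skipped with a warning; detection outputs are still written.
#'
#' @param config a [pipeline_config()].
#' @param stack optional in-memory H x W x T array (otherwise read from
#'   `config$input`).
#' @return invisibly, a list with `rois`, `roi_set`, `traces`,
#'   `traces_denoised`, `clusters`, `active_cluster`, `manifest`.
#' @export
run_pipeline <- function(config, stack = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stack <- if (is.null(stack)) {
    if (is.null(config$input)) stopf("no input: set config$input or pass a stack")
    read_stack(config$input)
  } else {
    as_stack(stack)
  }
  d <- dim(stack)
  nb <- config$baseline_frames
  if (nb >= d[3L]) {
    stopf("compute_dff: baseline (%d frames) leaves no frames to analyze (T = %d)",
          nb, d[3L])
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  dff <- run_stage("compute_dff", compute_dff(stack, nb))
  post_idx <- (nb + 1L):d[3L]
  rois <- run_stage("determine_rois",
                    determine_rois(dff[, , post_idx, drop = FALSE],
                                   config$params))
  rset <- run_stage("label_rois", label_rois(rois))
  k <- nrow(rset$table)

  traces <- traces_ss <- clusters <- active <- NULL
  if (k >= 1L) {
    traces <- run_stage("roi_trace", roi_traces(stack, rset, nb))
    noise <- run_stage("noise_trace", noise_trace(dff, rois))
    traces_ss <- traces
    if (d[3L] >= config$stft$nperseg) {
      for (j in seq_len(k)) {
        traces_ss[, j] <- run_stage("spectral_subtract",
                                    spectral_subtract(traces[, j], noise,
                                                      config$stft))
      }
    } else {
      warning("recording shorter than one STFT segment; skipping spectral subtraction")
    }
  }
  if (k >= 3L) {
    post_tr <- t(traces_ss[post_idx, , drop = FALSE])
    clusters <- run_stage("cluster", tryCatch(
      cluster_roi_traces(post_tr,
                         variance_threshold = config$variance_threshold,
                         k_min = config$k_min, k_max = config$k_max,
                         nstart = config$nstart, seed = config$seed),
      error = function(e) {
        warning(sprintf("clustering skipped: %s", conditionMessage(e)))
        NULL
      }))
    if (!is.null(clusters)) {
      kept <- attr(clusters, "kept")
      active <- active_cluster(clusters, post_tr[kept, , drop = FALSE])
    }
  } else if (k > 0L) {
    warning("fewer than 3 ROIs; clustering skipped")
  } else {
    warning("empty ROI mask; trace and clustering stages skipped")
  }

  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_rois(rset, out)
  if (!is.null(traces)) {
    write_traces(traces, file.path(out, "traces_raw.csv"))
    write_traces(traces_ss, file.path(out, "traces_denoised.csv"))
  }
  if (!is.null(clusters)) {
    kept <- attr(clusters, "kept")
    jsonlite::write_json(
      list(k = clusters$k,
           silhouette = as.list(clusters$silhouette),
           n_components = clusters$n_components,
           labels = data.frame(roi_label = rset$table$label[kept],
                               cluster = unname(clusters$labels)),
           active_cluster = active),
      file.path(out, "clusters.json"), auto_unbox = TRUE, digits = NA)
    write.csv(t(clusters$cluster_means), file.path(out, "cluster_means.csv"),
              row.names = FALSE)
  }
  manifest <- list(
    package = "lensroi",
    version = as.character(packageVersion("lensroi")),
    input = config$input %||% "<in-memory stack>",
    stack_dim = d,
    baseline_frames = nb,
    params = unclass(config$params),
    stft = unclass(config$stft),
    variance_threshold = config$variance_threshold,
    k_min = config$k_min, k_max = config$k_max, nstart = config$nstart,
    seed = config$seed,
    n_roi = k,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(rois = rois, roi_set = rset, traces = traces,
                 traces_denoised = traces_ss, clusters = clusters,
                 active_cluster = active, manifest = manifest))
}
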