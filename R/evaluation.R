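#' Detection accuracy of an ROI mask against ground truth
#'
#' A neuron counts as detected when its center pixel lies inside some ROI
#' (no tolerance radius). Fractions are reported per activity pattern and
#' for the active group (pattern 1 union pattern 2); patterns with no
#' neurons are omitted rather than reported as zero.
#'
#' @param rois a `roi_set`, `roi_mask`, or binary matrix.
#' @param neurons a `neuron_spec` data.frame (0-based `x_px`, `y_px`
#'   coordinates, `z_px`, `pattern`).
#' @return object of class `accuracy_report`: `per_pattern` data.frame
#'   (`pattern`, `n`, `detected`, `fraction`), `active` list
#'   (`n`, `detected`, `fraction`), and the per-neuron `neurons` table with
#'   a `detected` flag.
#' @export
detection_accuracy <- function(rois, neurons) {
  labels <- if (inherits(rois, "roi_set")) {
    rois$labels
  } else if (inherits(rois, "roi_mask")) {
    label_components(rois$mask, 8)
  } else {
    label_components(rois, 8)
  }
  H <- nrow(labels)
  W <- ncol(labels)
  nn <- as.data.frame(neurons)
  if (nrow(nn) && (any(nn$y_px < 0 | nn$y_px >= H) ||
                   any(nn$x_px < 0 | nn$x_px >= W))) {
    stopf("neuron coordinates outside the %d x %d mask", H, W)
  }
  nn$detected <- if (nrow(nn)) {
    labels[cbind(nn$y_px + 1L, nn$x_px + 1L)] > 0L
  } else {
    logical(0)
  }
  pats <- unique(nn$pattern)
  per_pattern <- do.call(rbind, lapply(pats, function(p) {
    sub <- nn[nn$pattern == p, ]
    data.frame(pattern = p, n = nrow(sub), detected = sum(sub$detected),
               fraction = mean(sub$detected), stringsAsFactors = FALSE)
  }))
  if (is.null(per_pattern)) {
    per_pattern <- data.frame(pattern = character(0), n = integer(0),
                              detected = integer(0), fraction = numeric(0))
  }
  act <- nn[nn$pattern %in% c("pattern1", "pattern2"), ]
  active <- if (nrow(act)) {
    list(n = nrow(act), detected = sum(act$detected),
         fraction = mean(act$detected))
  } else {
    list(n = 0L, detected = 0L, fraction = NA_real_)
  }
  structure(list(per_pattern = per_pattern, active = active, neurons = nn),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Detection accuracy (neuron center inside an ROI):\n")
  print(x$per_pattern, row.names = FALSE)
  if (!is.na(x$active$fraction)) {
    cat(sprintf("  active (pattern1+pattern2): %d/%d = %.3f\n",
                x$active$detected, x$active$n, x$active$fraction))
  }
  invisible(x)
}

#' Replicate simulation study of detection accuracy
#'
#' For each seed: simulate a dataset, baseline it, run the ROI pipeline on
#' the post-stimulation dF/F frames, and score detection against ground
#' truth. Summarizes the fraction of replicates that capture 100\% and at
#' least 90\% of the active neurons (with Clopper-Pearson 95\% CIs) and the
#' full accuracy histogram in 10\% bins (right-inclusive at 100\%).
#'
#' @param config a [sim_config()] used for every replicate (its seed is
#'   replaced per replicate).
#' @param params an [algorithm_params()].
#' @param n_replicates number of replicate simulations.
#' @param seeds integer vector of per-replicate seeds; default
#'   `base + 0:(n-1)` where `base` is `config$seed` (or 1).
#' @return object of class `replicate_study`: per-replicate `results`
#'   data.frame, `histogram` of active-detection fractions, `prop_100` /
#'   `prop_90` with their CIs, and pooled detected/undetected neuron tables.
#' @export
replicate_study <- function(config, params = algorithm_params(),
                            n_replicates = 100L, seeds = NULL) {
  stopifnot(inherits(config, "sim_config"))
  check_scalar_number(n_replicates, "n_replicates", 1, Inf, integer = TRUE)
  seeds <- seeds %||% ((config$seed %||% 1L) + seq_len(n_replicates) - 1L)
  if (length(seeds) != n_replicates) stopf("need one seed per replicate")

  res <- vector("list", n_replicates)
  pooled <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- seeds[i]
    ds <- simulate_dataset(cfg)
    dff <- compute_dff(ds$frames, cfg$n_pre_frames)
    post <- dff[, , cfg$n_pre_frames + seq_len(cfg$n_post_frames),
                drop = FALSE]
    rm(dff)
    rois <- determine_rois(post, params)
    rm(post)
    rep_i <- detection_accuracy(rois, ds$neurons)
    nn <- rep_i$neurons
    nn$replicate <- i
    nn$seed <- seeds[i]
    pooled[[i]] <- nn
    pp <- rep_i$per_pattern
    frac_of <- function(p) if (p %in% pp$pattern) pp$fraction[pp$pattern == p]
                           else NA_real_
    res[[i]] <- data.frame(
      replicate = i, seed = seeds[i],
      n_roi = rois$n_roi, mean_roi_area = rois$mean_roi_area,
      n_active = rep_i$active$n, detected_active = rep_i$active$detected,
      frac_active = rep_i$active$fraction,
      frac_pattern1 = frac_of("pattern1"),
      frac_pattern2 = frac_of("pattern2"),
      frac_unresponsive = frac_of("unresponsive")
    )
    rm(ds, rois)
  }
  results <- do.call(rbind, res)
  pooled <- do.call(rbind, pooled)

  frac <- results$frac_active
  ok <- !is.na(frac)
  n_ok <- sum(ok)
  n100 <- sum(frac[ok] >= 1 - 1e-9)
  n90 <- sum(frac[ok] >= 0.9 - 1e-9)
  bins <- pmin(floor(frac[ok] * 10) + 1L, 10L)  # [0,10)...[90,100]
  histo <- tabulate(bins, nbins = 10L)
  names(histo) <- paste0(seq(0, 90, 10), "-", seq(10, 100, 10), "%")
  ci <- function(k, n) if (n > 0) as.numeric(binom.test(k, n)$conf.int)
                       else c(NA_real_, NA_real_)

  structure(list(
    results = results,
    histogram = histo,
    n_replicates = n_replicates,
    n_scored = n_ok,
    prop_100 = if (n_ok) n100 / n_ok else NA_real_,
    ci_100 = ci(n100, n_ok),
    prop_90 = if (n_ok) n90 / n_ok else NA_real_,
    ci_90 = ci(n90, n_ok),
    neurons = pooled,
    params = params,
    config = config,
    seeds = seeds
  ), class = "replicate_study")
}

#' @export
print.replicate_study <- function(x, ...) {
  cat(sprintf("Replicate detection study: %d replicate(s), %d scored\n",
              x$n_replicates, x$n_scored))
  cat(sprintf("  100%% active capture: %.3f (95%% CI %.3f-%.3f)\n",
              x$prop_100, x$ci_100[1], x$ci_100[2]))
  cat(sprintf("  >=90%% active capture: %.3f (95%% CI %.3f-%.3f)\n",
              x$prop_90, x$ci_90[1], x$ci_90[2]))
  cat("  histogram of active-capture fractions:\n")
  print(x$histogram)
  invisible(x)
}

#' @export
plot.replicate_study <- function(x, ...) {
  barplot(x$histogram, las = 2, ylab = "replicates",
          main = "Active-neuron capture fraction", ...)
  invisible(x)
}

#' Depth distribution of undetected neurons
#'
#' Pools the active (pattern 1 / pattern 2) neurons across replicates and
#' compares the depths of undetected versus detected ones. With a lensless
#' sensor the point-spread footprint widens and dims with depth, so missed
#' neurons are expected to sit farther from the sensor.
#'
#' @param reports a `replicate_study`, or a list of `accuracy_report`s.
#' @return object of class `depth_analysis`: `depth_counts` data.frame
#'   (`z_px`, `n_undetected`, `n_detected`), `mean_depth_undetected`,
#'   `mean_depth_detected` (NA when a group is empty), `n_undetected`,
#'   `n_detected`.
#' @export
undetected_depth_analysis <- function(reports) {
  nn <- if (inherits(reports, "replicate_study")) {
    reports$neurons
  } else if (is.list(reports) &&
             all(vapply(reports, inherits, logical(1), "accuracy_report"))) {
    do.call(rbind, lapply(reports, `[[`, "neurons"))
  } else {
    stopf("'reports' must be a replicate_study or list of accuracy_report")
  }
  act <- nn[nn$pattern %in% c("pattern1", "pattern2"), , drop = FALSE]
  und <- act[!act$detected, , drop = FALSE]
  det <- act[act$detected, , drop = FALSE]
  zs <- sort(unique(act$z_px))
  depth_counts <- data.frame(
    z_px = zs,
    n_undetected = vapply(zs, function(z) sum(und$z_px == z), integer(1)),
    n_detected = vapply(zs, function(z) sum(det$z_px == z), integer(1))
  )
  structure(list(
    depth_counts = depth_counts,
    mean_depth_undetected = if (nrow(und)) mean(und$z_px) else NA_real_,
    mean_depth_detected = if (nrow(det)) mean(det$z_px) else NA_real_,
    n_undetected = nrow(und),
    n_detected = nrow(det)
  ), class = "depth_analysis")
}

#' @export
print.depth_analysis <- function(x, ...) {
  cat(sprintf("Missed-neuron depth analysis: %d undetected, %d detected active neurons\n",
              x$n_undetected, x$n_detected))
  if (x$n_undetected) {
    print(x$depth_counts, row.names = FALSE)
    cat(sprintf("  mean depth: undetected %.2f px vs detected %.2f px\n",
                x$mean_depth_undetected, x$mean_depth_detected))
  }
  invisible(x)
}

#' Run the ROI pipeline over a grid of parameter settings
#'
#' @param dff H x W x T percent dF/F array.
#' @param grid data.frame with columns `sigma1`, `fp1`, `area1`, `sigma2`,
#'   `fp2`, `area2`, `time_frames`.
#' @param block_size adaptive-threshold window side used for every run.
#' @return the grid with `mean_roi_area` and `n_roi` columns appended
#'   (0 and 0 for settings producing an empty mask).
#' @export
parameter_sweep <- function(dff, grid, block_size = 15L) {
  need <- c("sigma1", "fp1", "area1", "sigma2", "fp2", "area2", "time_frames")
  if (!is.data.frame(grid) || nrow(grid) == 0L || !all(need %in% names(grid))) {
    stopf("'grid' must be a nonempty data.frame with columns %s",
          paste(need, collapse = ", "))
  }
  dff <- as_stack(dff, "dff")
  out <- grid
  out$mean_roi_area <- NA_real_
  out$n_roi <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    p <- algorithm_params(
      sigma1 = grid$sigma1[i], fp1 = grid$fp1[i], area1 = grid$area1[i],
      sigma2 = grid$sigma2[i], fp2 = grid$fp2[i], area2 = grid$area2[i],
      time_frames = grid$time_frames[i], block_size = block_size
    )
    r <- determine_rois(dff, p)
    out$mean_roi_area[i] <- r$mean_roi_area
    out$n_roi[i] <- r$n_roi
  }
  out
}

#' Default parameter grid for sensitivity sweeps
#'
#' Factorial grid over sigma in \{0.5, 1.5, 2.5\} (both passes), footprint
#' in \{1, 2, 3\} (both passes), area in \{0, 9\} (both passes) and the
#' supplied `time_frames` levels; optionally a random subsample of the
#' (large) full factorial.
#'
#' @param time_frames_levels integer vector of `time_frames` levels.
#' @param sample_n optional number of rows to sample from the factorial.
#' @param seed seed for the subsample.
#' @return data.frame usable as the `grid` of [parameter_sweep()].
#' @export
default_parameter_grid <- function(time_frames_levels, sample_n = NULL,
                                   seed = NULL) {
  grid <- expand.grid(
    sigma1 = c(0.5, 1.5, 2.5), fp1 = 1:3, area1 = c(0, 9),
    sigma2 = c(0.5, 1.5, 2.5), fp2 = 1:3, area2 = c(0, 9),
    time_frames = as.integer(time_frames_levels),
    KEEP.OUT.ATTRS = FALSE
  )
  if (!is.null(sample_n)) {
    check_scalar_number(sample_n, "sample_n", 1, nrow(grid), integer = TRUE)
    grid <- with_seed(seed, grid[sample(nrow(grid), sample_n), , drop = FALSE])
    rownames(grid) <- NULL
  }
  grid
}

#' Partial least squares sensitivity model of the algorithm parameters
#'
#' Fits a PLS regression of mean ROI area on the seven raw-unit pipeline
#' parameters from a [parameter_sweep()] table, the same analysis used to
#' rank how each parameter drives ROI size. Reports per-parameter
#' coefficients on the response scale, the intercept, in-sample R-squared,
#' and the relative prediction deviation (RPD = SD(response) / RMSE of
#' leave-one-out prediction).
#'
#' @param sweep_table output of [parameter_sweep()].
#' @param n_components number of latent PLS components.
#' @return object of class `pls_model` with `coefficients` (length 7,
#'   named), `intercept`, `r_squared`, `rpd`, `n_components`, `fitted`.
#' @export
pls_parameter_model <- function(sweep_table, n_components = 2L) {
  need <- c("sigma1", "fp1", "area1", "sigma2", "fp2", "area2", "time_frames")
  if (!all(c(need, "mean_roi_area") %in% names(sweep_table))) {
    stopf("'sweep_table' must contain %s and mean_roi_area",
          paste(need, collapse = ", "))
  }
  check_scalar_number(n_components, "n_components", 1, Inf, integer = TRUE)
  X <- as.matrix(sweep_table[, need])
  y <- sweep_table$mean_roi_area
  if (nrow(X) < n_components + 2L) {
    stopf("need at least n_components + 2 = %d rows", n_components + 2L)
  }
  const <- need[apply(X, 2L, function(v) diff(range(v)) == 0)]
  if (length(const)) {
    stopf("constant predictor column(s): %s", paste(const, collapse = ", "))
  }
  if (sd(y) == 0) {
    # nothing to explain: flat model
    return(structure(list(
      coefficients = setNames(numeric(7L), need),
      intercept = y[1L],
      r_squared = 0,
      rpd = Inf,
      n_components = as.integer(n_components),
      fitted = rep(y[1L], length(y))
    ), class = "pls_model"))
  }
  fit <- fit_pls(X, y, n_components)
  fitted <- fit$predict(X)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0

  loo <- vapply(seq_len(nrow(X)), function(i) {
    f <- fit_pls(X[-i, , drop = FALSE], y[-i], n_components)
    f$predict(X[i, , drop = FALSE])
  }, numeric(1))
  rmsep <- sqrt(mean((y - loo)^2))
  rpd <- if (rmsep > 0) sd(y) / rmsep else Inf

  structure(list(
    coefficients = fit$coefficients,
    intercept = fit$intercept,
    r_squared = r2,
    rpd = rpd,
    n_components = as.integer(n_components),
    fitted = fitted
  ), class = "pls_model")
}

# PLS fit via mixOmics with raw-unit coefficients recovered by probing the
# affine predictor at zero and at the unit vectors.
fit_pls <- function(X, y, ncomp) {
  vars <- colnames(X)
  m <- suppressMessages(
    mixOmics::pls(X, matrix(y, ncol = 1L), ncomp = ncomp, mode = "regression")
  )
  predict_raw <- function(newX) {
    newX <- matrix(newX, ncol = length(vars),
                   dimnames = list(NULL, vars))
    p <- predict(m, newX)$predict
    as.numeric(p[, 1L, ncomp])
  }
  b0 <- predict_raw(matrix(0, 1L, length(vars)))
  coefs <- vapply(seq_along(vars), function(j) {
    e <- matrix(0, 1L, length(vars))
    e[1L, j] <- 1
    predict_raw(e) - b0
  }, numeric(1))
  names(coefs) <- vars
  list(coefficients = coefs, intercept = b0, predict = predict_raw)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS sensitivity model (%d component(s)): R^2 = %.4f, RPD = %.3f\n",
              x$n_components, x$r_squared, x$rpd))
  cat("  coefficients (response units per parameter unit):\n")
  print(round(x$coefficients, 4))
  cat(sprintf("  intercept: %.4f\n", x$intercept))
  invisible(x)
}
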