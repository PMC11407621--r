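make_neurons <- function(x, y, z, pattern) {
  data.frame(id = seq_along(x), x_px = x, y_px = y, z_px = z, z_um = z * 7.5,
             pattern = pattern, stringsAsFactors = FALSE)
}

test_that("detection accuracy counts neuron centers inside ROIs", {
  mask <- matrix(0, 20, 15)
  mask[3:6, 3:6] <- 1      # covers neurons at rows 3-6, cols 3-6 (1-based)
  nn <- make_neurons(x = c(3, 4, 10), y = c(3, 4, 10), z = c(4, 6, 8),
                     pattern = c("pattern1", "pattern2", "pattern1"))
  rep <- detection_accuracy(mask, nn)
  expect_equal(rep$active$n, 3L)
  expect_equal(rep$active$detected, 2L)
  expect_equal(rep$active$fraction, 2 / 3)
  pp <- rep$per_pattern
  expect_equal(pp$fraction[pp$pattern == "pattern1"], 0.5)
  expect_equal(pp$fraction[pp$pattern == "pattern2"], 1)
  # absent patterns are omitted, not reported as zero
  expect_false("unresponsive" %in% pp$pattern)

  # every neuron covered / empty mask
  full <- detection_accuracy(matrix(1, 20, 15), nn)
  expect_true(all(full$per_pattern$fraction == 1))
  none <- detection_accuracy(matrix(0, 20, 15), nn)
  expect_true(all(none$per_pattern$fraction == 0))

  # a mask covering exactly 7 of 10 pattern-1 neurons
  nn10 <- make_neurons(x = rep(2:11, 1), y = rep(5L, 10), z = rep(5L, 10),
                       pattern = rep("pattern1", 10))
  m7 <- matrix(0, 20, 15)
  m7[6, 3:9] <- 1  # columns 3..9 cover x = 2..8
  expect_equal(detection_accuracy(m7, nn10)$active$fraction, 0.7)

  # invariant to ROI labeling order (same mask, permuted construction)
  expect_equal(detection_accuracy(label_rois(mask), nn)$active$fraction, 2 / 3)
})

test_that("replicate studies are reproducible and summarized correctly", {
  cfg <- tiny_config()
  p <- algorithm_params(block_size = 9L)
  s1 <- replicate_study(cfg, p, n_replicates = 2L, seeds = c(5L, 6L))
  s2 <- replicate_study(cfg, p, n_replicates = 2L, seeds = c(5L, 6L))
  expect_identical(s1$results, s2$results)
  expect_equal(nrow(s1$results), 2L)
  expect_equal(sum(s1$histogram), s1$n_scored)
  expect_true(all(s1$results$frac_active >= 0 & s1$results$frac_active <= 1,
                  na.rm = TRUE))
  expect_true(is.na(s1$prop_100) ||
              (s1$prop_100 >= s1$ci_100[1] - 1e-9 &&
               s1$prop_100 <= s1$ci_100[2] + 1e-9))
  # histogram bins are 10% wide with [90%, 100%] right-inclusive
  expect_equal(s1$histogram[[10]],
               sum(s1$results$frac_active >= 0.9 - 1e-9, na.rm = TRUE))
})

test_that("depth analysis pools undetected active neurons", {
  nn <- make_neurons(x = c(6, 7, 8), y = c(6, 7, 8), z = c(4L, 8L, 8L),
                     pattern = c("pattern1", "pattern1", "pattern2"))
  mask <- matrix(0, 20, 15)
  mask[7, 7] <- 1  # detects only the z=4 neuron at (6,6)
  rep1 <- detection_accuracy(mask, nn)
  da <- undetected_depth_analysis(list(rep1, rep1))
  expect_equal(da$n_undetected, 4L)                 # two misses, two reports
  expect_true(all(da$depth_counts$n_undetected[da$depth_counts$z_px == 8] == 4))
  expect_equal(da$mean_depth_undetected, 8)
  expect_equal(da$mean_depth_detected, 4)

  # no undetected neurons -> empty distribution, NA means
  all_in <- detection_accuracy(matrix(1, 20, 15), nn)
  da0 <- undetected_depth_analysis(list(all_in))
  expect_equal(da0$n_undetected, 0L)
  expect_true(is.na(da0$mean_depth_undetected))
})

test_that("parameter sweeps record per-setting mask statistics", {
  ds <- simulate_dataset(tiny_config(seed = 2L))
  dff <- compute_dff(ds$frames, 100L)
  post <- dff[, , 101:400]
  grid1 <- data.frame(sigma1 = 1.5, fp1 = 3L, area1 = 0, sigma2 = 1.5,
                      fp2 = 3L, area2 = 0, time_frames = 300L)
  sw <- parameter_sweep(post, grid1, block_size = 9L)
  direct <- determine_rois(post, algorithm_params(block_size = 9L))
  expect_equal(sw$mean_roi_area, direct$mean_roi_area)
  expect_equal(sw$n_roi, direct$n_roi)

  # a constant stack gives an empty mask -> area 0, count 0
  const <- array(1, c(20, 12, 5))
  g0 <- data.frame(sigma1 = 1.5, fp1 = 3L, area1 = 0, sigma2 = 1.5,
                   fp2 = 3L, area2 = 0, time_frames = 5L)
  sw0 <- parameter_sweep(const, g0, block_size = 7L)
  expect_equal(sw0$mean_roi_area, 0)
  expect_equal(sw0$n_roi, 0L)

  expect_error(parameter_sweep(post, data.frame()), "grid")
  g <- default_parameter_grid(c(10L, 20L), sample_n = 12L, seed = 1L)
  expect_equal(nrow(g), 12L)
  expect_true(all(g$fp1 %in% 1:3))
})

test_that("PLS recovers a linear parameter effect and rejects constant columns", {
  set.seed(10)
  grid <- default_parameter_grid(c(10L, 30L, 60L), sample_n = 40L, seed = 3L)
  # response exactly linear in sigma2: with enough latent components PLS
  # reaches the least-squares fit and recovers the true slope
  grid$mean_roi_area <- 5 + 3 * grid$sigma2
  m <- pls_parameter_model(grid, n_components = 5L)
  expect_gt(m$r_squared, 0.999)
  expect_equal(unname(m$coefficients["sigma2"]), 3, tolerance = 1e-3)
  expect_lt(max(abs(m$coefficients[setdiff(names(m$coefficients), "sigma2")])),
            0.01)
  expect_gt(m$rpd, 1)

  # constant response: no explainable variance, coefficients ~ 0
  grid2 <- grid
  grid2$mean_roi_area <- 7
  m2 <- pls_parameter_model(grid2, n_components = 2L)
  expect_lt(abs(m2$r_squared), 1e-9)
  expect_lt(max(abs(m2$coefficients)), 1e-9)

  grid3 <- grid
  grid3$area1 <- 0
  expect_error(pls_parameter_model(grid3), "area1")
})
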