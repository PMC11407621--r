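test_that("sampled neurons respect the configured ranges and patterns", {
  cfg <- sim_config(seed = 11L)
  set.seed(11)
  nn <- sample_neurons(cfg)
  expect_equal(nrow(nn), 30L)
  expect_true(all(nn$x_px >= 5 & nn$x_px <= 35))
  expect_true(all(nn$y_px >= 5 & nn$y_px <= 115))
  expect_true(all(nn$z_px >= 4 & nn$z_px <= 8))
  expect_true(all(nn$pattern %in% c("pattern1", "pattern2", "unresponsive")))
  # depth in physical units spans 30-60 um under defaults
  expect_true(all(nn$z_um >= 30 & nn$z_um <= 60))

  empty <- sim_config(n_neurons = 0L)
  set.seed(1)
  expect_equal(nrow(sample_neurons(empty)), 0L)

  set.seed(5)
  a <- sample_neurons(cfg)
  set.seed(5)
  b <- sample_neurons(cfg)
  expect_identical(a, b)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(x_range = c(2, 35)), "x_range")
  expect_error(sim_config(y_range = c(5, 118)), "y_range")
  expect_error(sim_config(spontaneous_fire_prob = 1.5), "spontaneous")
  expect_error(sim_config(n_post_frames = 0), "n_post_frames")
})

test_that("pattern schedules tile the post window in the documented order", {
  s1 <- pattern_schedule("pattern1", 36000L)
  expect_equal(length(s1), 36000L)
  expect_equal(unname(table(s1)[c("high", "medium", "low")]),
               c(6000L, 12000L, 18000L), ignore_attr = TRUE)
  expect_equal(unique(s1[1:6000]), "high")
  s2 <- pattern_schedule("pattern2", 36000L)
  expect_equal(unique(s2[1:6000]), "medium")
  expect_equal(unique(s2[6001:12000]), "high")
  expect_equal(unique(s2[24001:36000]), "low")
  expect_equal(unique(pattern_schedule("unresponsive", 100L)), "spontaneous")
  expect_error(pattern_schedule("bogus", 100L), "unknown")
})

test_that("spontaneous firing matches the configured per-frame probability", {
  cfg <- sim_config(n_pre_frames = 6000L, n_post_frames = 6000L,
                    n_neurons = 2L)
  nn <- data.frame(id = 1:2, x_px = c(10L, 20L), y_px = c(10L, 20L),
                   z_px = c(5L, 6L), z_um = c(37.5, 45),
                   pattern = c("unresponsive", "unresponsive"))
  set.seed(42)
  sp <- generate_spike_trains(nn, cfg)
  expect_equal(dim(sp), c(2L, 12000L))
  # 12000 frames per neuron, p = 0.10: within 3 standard errors
  se <- sqrt(0.1 * 0.9 / 12000)
  for (i in 1:2) expect_lt(abs(mean(sp[i, ]) - 0.10), 3 * se)

  cfg0 <- sim_config(n_pre_frames = 500L, n_post_frames = 500L,
                     n_neurons = 1L, spontaneous_fire_prob = 0)
  set.seed(1)
  sp0 <- generate_spike_trains(nn[1, ], cfg0)
  expect_true(all(sp0 == 0))
})

test_that("event rates per activity level are preserved by the frame mapping", {
  cfg <- sim_config(n_pre_frames = 10L, n_post_frames = 12000L,
                    n_neurons = 1L)
  set.seed(7)
  for (pat in c("pattern1", "pattern2")) {
    nn <- data.frame(id = 1L, x_px = 10L, y_px = 10L, z_px = 5L,
                     z_um = 37.5, pattern = pat)
    sp <- generate_spike_trains(nn, cfg)
    sched <- pattern_schedule(pat, 12000L)
    pp <- activity_levels()
    for (lev in c("high", "medium", "low")) {
      idx <- which(sched == lev) + 10L
      row <- pp[pp$level == lev, ]
      # expected spikes/frame: (rate/fps) * (1 - bp + bp * mean burst size)
      exp_rate <- row$rate_hz / cfg$fps *
        (1 - row$burst_prob + row$burst_prob * mean(row$burst_min:row$burst_max))
      emp <- mean(sp[1, idx])
      # Poisson-compound SE, approximated via the empirical variance
      se <- sd(sp[1, idx]) / sqrt(length(idx))
      expect_lt(abs(emp - exp_rate), 4 * se)
    }
  }
})

test_that("pattern-1 neurons fire more early than late after stimulation", {
  cfg <- sim_config(n_pre_frames = 10L, n_post_frames = 3600L,
                    n_neurons = 10L)
  nn <- data.frame(id = 1:10, x_px = 10L, y_px = 10L, z_px = 5L,
                   z_um = 37.5, pattern = "pattern1")
  set.seed(3)
  sp <- generate_spike_trains(nn, cfg)
  post <- sp[, 11:3610]
  first_sixth <- rowMeans(post[, 1:600])
  last_half <- rowMeans(post[, 1801:3600])
  expect_true(all(first_sixth > last_half))
})

test_that("rendering follows the point-source model", {
  cfg0 <- tiny_config(noise_sd = 0, background_noise_sd = 0,
                      gradient_amplitude = 0)
  nn <- data.frame(id = 1L, x_px = 10L, y_px = 30L, z_px = 4L, z_um = 30,
                   pattern = "unresponsive")
  # no spikes, no noise -> constant baseline everywhere
  sp0 <- matrix(0L, 1L, 400L)
  fr0 <- render_frames(sp0, nn, cfg0)
  expect_true(all(fr0 == cfg0$baseline_offset))

  # single spike -> brightest pixel of the difference image under the source
  sp1 <- sp0
  sp1[1, 200] <- 1L
  fr1 <- render_frames(sp1, nn, cfg0)
  dimg <- fr1[, , 200] - fr0[, , 200]
  peak <- which(dimg == max(dimg), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(nn$y_px + 1L, nn$x_px + 1L))

  # shallower source is brighter at its peak than a deeper one
  nn8 <- transform(nn, z_px = 8L)
  fr8 <- render_frames(sp1, nn8, cfg0)
  expect_gt(max(fr1[, , 200]) - cfg0$baseline_offset,
            max(fr8[, , 200]) - cfg0$baseline_offset)
})

test_that("peak amplitude decreases monotonically with depth (noise off)", {
  cfg <- tiny_config(noise_sd = 0, background_noise_sd = 0,
                     gradient_amplitude = 0)
  sp <- matrix(0L, 1L, 10L)
  sp[1, 5] <- 1L
  peaks <- vapply(4:8, function(z) {
    nn <- data.frame(id = 1L, x_px = 12L, y_px = 30L, z_px = z,
                     z_um = z * 7.5, pattern = "unresponsive")
    max(render_frames(sp, nn, cfg)[, , 5]) - cfg$baseline_offset
  }, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("simulated datasets have the configured shape and reproduce bit-identically", {
  cfg <- tiny_config(seed = 9L)
  ds1 <- simulate_dataset(cfg)
  expect_equal(dim(ds1$frames), c(60L, 24L, 400L))
  expect_equal(attr(ds1$frames, "n_pre_frames"), 100L)
  expect_true(all(is.finite(ds1$frames)) && min(ds1$frames) >= 0)
  expect_equal(dim(ds1$spikes), c(6L, 400L))
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds1$frames, ds2$frames)
  expect_identical(ds1$neurons, ds2$neurons)

  # full default design shape (metadata only, no rendering): pre+post frames
  dcfg <- sim_config()
  expect_equal(dcfg$n_pre_frames + dcfg$n_post_frames, 45000L)
  expect_equal(c(dcfg$height_px, dcfg$width_px), c(120L, 40L))
})
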