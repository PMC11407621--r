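test_that("percent dF/F matches element-wise recomputation", {
  set.seed(1)
  st <- array(runif(10 * 4 * 4, 10, 50), c(4, 4, 10))
  dff <- compute_dff(st, 3L)
  ref <- array(0, dim(st))
  for (i in 1:4) for (j in 1:4) {
    f0 <- mean(st[i, j, 1:3])
    for (t in 1:10) ref[i, j, t] <- 100 * (st[i, j, t] - f0) / f0
  }
  expect_equal(dff, ref, ignore_attr = TRUE, tolerance = 1e-12)

  # F_t = F_0 gives exactly 0; simple arithmetic case gives 50%
  st2 <- array(50, c(2, 2, 4))
  st2[1, 1, 3] <- 75
  d2 <- compute_dff(st2, 2L)
  expect_equal(d2[1, 1, 1], 0)
  expect_equal(d2[1, 1, 3], 50)

  # zero-baseline pixels map to 0 with a warning
  st3 <- st2
  st3[2, 2, ] <- 0
  expect_warning(d3 <- compute_dff(st3, 2L), "zero baseline")
  expect_true(all(d3[2, 2, ] == 0) && all(is.finite(d3)))

  expect_error(compute_dff(st2, 9L), "n_baseline_frames")
})

test_that("adaptive binarization equals the brute-force Gaussian threshold", {
  set.seed(2)
  for (rep in 1:10) {
    img <- matrix(rnorm(16 * 16), 16, 16)
    for (prm in list(c(1.5, 5), c(0.8, 7), c(2.5, 9))) {
      expect_equal(adaptive_binarize(img, prm[1], prm[2]),
                   oracle_binarize(img, prm[1], prm[2]))
    }
  }
  # constant image: threshold equals value, strict inequality -> all zero
  expect_true(all(adaptive_binarize(matrix(3, 9, 9), 1.5, 5) == 0))
  # single hot pixel exceeds its own Gaussian-weighted mean
  z <- matrix(0, 11, 11)
  z[6, 6] <- 10
  expect_equal(adaptive_binarize(z, 1.5, 5)[6, 6], 1)
  expect_error(adaptive_binarize(z, 1.5, 4), "odd")
})

test_that("morphological opening equals brute-force erosion/dilation", {
  set.seed(3)
  for (rep in 1:10) {
    b <- random_binary(16, 16)
    for (fp in c(2, 3, 5)) {
      expect_equal(morphological_opening(b, fp), oracle_opening(b, fp))
    }
  }
  # isolated pixel is removed by a 3-px footprint
  m <- matrix(0, 8, 8)
  m[4, 4] <- 1
  expect_true(all(morphological_opening(m, 3) == 0))
  # all-ones: interior survives, the zero-padded border ring erodes
  ones <- matrix(1, 8, 8)
  o <- morphological_opening(ones, 3)
  expect_equal(o, oracle_opening(ones, 3))
  expect_true(all(o[2:7, 2:7] == 1))
  # footprint 1 is the identity
  b <- random_binary(10, 10)
  expect_equal(morphological_opening(b, 1), b)
})

test_that("area opening removes components strictly below the threshold", {
  set.seed(4)
  for (rep in 1:10) {
    b <- random_binary(16, 16, 0.35)
    for (a in c(2, 5, 9)) {
      expect_equal(area_opening(b, a), oracle_area_open(b, a))
    }
  }
  b <- random_binary(12, 12)
  expect_equal(area_opening(b, 0), b)
  # components of size 4 and 16 with min_area 9
  m <- matrix(0, 12, 12)
  m[1:2, 1:2] <- 1
  m[6:9, 6:9] <- 1
  r <- area_opening(m, 9)
  expect_equal(sum(r), 16)
  expect_true(all(r[6:9, 6:9] == 1))
  # a component of exactly min_area pixels is retained
  expect_equal(area_opening(m, 4), m)
})

test_that("opening and area opening are idempotent and anti-extensive", {
  set.seed(5)
  for (rep in 1:20) {
    b <- random_binary(16, 16)
    o <- morphological_opening(b, 3)
    expect_true(all(o <= b))                       # anti-extensive
    expect_equal(morphological_opening(o, 3), o)   # idempotent
    a <- area_opening(b, 5)
    expect_true(all(a <= b))
    expect_equal(area_opening(a, 5), a)
  }
})

test_that("foreground mass shrinks as the opening footprint grows", {
  # opening by a larger square structuring element is pointwise smaller
  set.seed(6)
  for (rep in 1:10) {
    b <- random_binary(20, 20, 0.6)
    o1 <- morphological_opening(b, 1)
    o3 <- morphological_opening(b, 3)
    o5 <- morphological_opening(b, 5)
    expect_true(all(o3 <= o1))
    expect_true(all(o5 <= o3))
  }
})

test_that("average_binary is the element-wise mean", {
  set.seed(7)
  frames <- lapply(1:10, function(i) random_binary(6, 6))
  avg <- average_binary(frames)
  ref <- Reduce(`+`, frames) / 10
  expect_equal(avg, ref)
  expect_true(all(avg >= 0 & avg <= 1))
  same <- replicate(4, frames[[1]], simplify = FALSE)
  expect_equal(average_binary(same), frames[[1]])
  expect_error(average_binary(list()), "empty")
})

test_that("the two-pass pipeline returns strictly binary masks and is deterministic", {
  ds <- simulate_dataset(tiny_config(seed = 4L))
  dff <- compute_dff(ds$frames, 100L)
  post <- dff[, , 101:400]
  p <- algorithm_params(block_size = 9L)
  r1 <- determine_rois(post, p)
  r2 <- determine_rois(post, p)
  expect_identical(r1$mask, r2$mask)
  expect_true(all(r1$mask %in% c(0, 1)))
  expect_true(all(r1$average_image >= 0 & r1$average_image <= 1))
  expect_equal(r1$mean_roi_area,
               if (r1$n_roi > 0) sum(r1$mask) / r1$n_roi else 0)

  # a constant stack yields an empty mask
  const <- array(5, c(20, 12, 8))
  r0 <- determine_rois(const, algorithm_params(block_size = 7L))
  expect_equal(r0$n_roi, 0L)
  expect_true(all(r0$mask == 0))

  # cleaning passes 6-7 are idempotent on the final mask
  again <- area_opening(morphological_opening(r1$mask, p$fp2), p$area2)
  expect_equal(again, r1$mask)

  expect_error(determine_rois(post, algorithm_params(time_frames = 9999L)),
               "time_frames")
})

test_that("pipeline steps match their composition on a small stack", {
  ds <- simulate_dataset(tiny_config(seed = 8L))
  dff <- compute_dff(ds$frames, 100L)
  sub <- dff[, , 101:130]
  p <- algorithm_params(sigma1 = 1.2, fp1 = 3L, area1 = 4,
                        sigma2 = 1.8, fp2 = 2L, area2 = 6,
                        block_size = 9L)
  cleaned <- lapply(1:30, function(t) {
    area_opening(morphological_opening(
      adaptive_binarize(sub[, , t], p$sigma1, p$block_size), p$fp1), p$area1)
  })
  avg <- average_binary(cleaned)
  manual <- area_opening(morphological_opening(
    adaptive_binarize(avg, p$sigma2, p$block_size), p$fp2), p$area2)
  auto <- determine_rois(sub, p)
  expect_equal(auto$average_image, avg)
  expect_equal(auto$mask, manual)
})

test_that("ROI labeling uses 8-connectivity and partitions the foreground", {
  empty <- label_rois(matrix(0, 5, 5))
  expect_equal(nrow(empty$table), 0L)

  diagm <- matrix(0, 5, 5)
  diagm[2, 2] <- 1
  diagm[3, 3] <- 1
  expect_equal(nrow(label_rois(diagm)$table), 1L)

  set.seed(8)
  for (rep in 1:10) {
    b <- random_binary(16, 16, 0.3)
    rs <- label_rois(b)
    expect_equal(sum(rs$table$area), sum(b))
    ref <- oracle_label(b, 8)
    expect_identical(rs$labels, ref)
  }
})

test_that("ROI traces implement the ROI-mean dF/F formula", {
  set.seed(9)
  st <- array(runif(8 * 6 * 12, 20, 80), c(8, 6, 12))
  px <- c(3L, 10L, 17L, 25L, 31L)  # a 5-pixel ROI
  tr <- roi_trace(st, px, 4L)
  M <- matrix(st, 48, 12)
  fbar <- colMeans(M[px, ])
  f0 <- mean(fbar[1:4])
  expect_equal(tr, 100 * (fbar - f0) / f0, tolerance = 1e-12)

  # constant over the ROI -> all-zero trace
  stc <- st
  stc[cbind(rep((px - 1) %% 8 + 1, 12), rep((px - 1) %/% 8 + 1, 12),
            rep(1:12, each = 5))] <- 42
  expect_true(all(abs(roi_trace(stc, px, 4L)) < 1e-12))

  # a single-pixel ROI reduces to that pixel's per-pixel dF/F
  one <- roi_trace(st, 3L, 4L)
  dff <- compute_dff(st, 4L)
  expect_equal(one, dff[3, 1, ], tolerance = 1e-12)

  expect_error(roi_trace(st * 0, px, 4L), "zero")
  expect_error(roi_trace(st, integer(0), 4L), "empty")

  # roi_traces agrees with per-ROI calls
  b <- matrix(0, 8, 6)
  b[c(3, 10, 17)] <- 1
  b[40:43] <- 1
  rs <- label_rois(b)
  tm <- roi_traces(st, rs, 4L)
  expect_equal(ncol(tm), nrow(rs$table))
  for (j in seq_len(ncol(tm))) {
    expect_equal(tm[, j], roi_trace(st, rs$pixels[[j]], 4L))
  }
})
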