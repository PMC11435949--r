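test_that("sliding standard deviation matches a brute-force oracle", {
  set.seed(6)
  mag <- matrix(stats::runif(4 * 1000), 4, 1000)
  p <- feature_params(window_w = 100L, step_s = 50L)
  expect_equal(sliding_std(mag, p), naive_sliding_std(mag, 100L, 50L),
               tolerance = 1e-12)
  ## population (divide-by-W) normalisation, not sample
  one <- matrix(c(1, 2, 3, 4), 1, 4)
  p2 <- feature_params(window_w = 4L, step_s = 4L)
  expect_equal(sliding_std(one, p2)[1, 1], sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
})

test_that("window-count geometry reproduces the printed configuration", {
  ## 6 s at 640 samples/s with W = 320, S = 64 -> 60 windows
  mag <- matrix(1, 2, 3840)
  out <- sliding_std(mag, feature_params())
  expect_identical(ncol(out), 60L)
  expect_true(all(out == 0))                    # constant rows have zero std
  expect_error(sliding_std(matrix(1, 2, 100), feature_params()), "N < window")
})

test_that("bin-window selection equals exhaustive search with first-offset ties", {
  set.seed(7)
  stdmat <- matrix(stats::runif(64 * 60), 64, 60)
  expect_identical(select_bin_window(stdmat, 40L),
                   as.integer(naive_select_bin_window(stdmat, 40L)))
  ## all mass in rows 11..50 (0-based 10..49)
  block <- matrix(0, 64, 10); block[11:50, ] <- 1
  expect_identical(select_bin_window(block, 40L), 10L)
  expect_identical(select_bin_window(matrix(1, 64, 5), 40L), 0L)
  expect_error(select_bin_window(matrix(1, 8, 4), 9L), "exceeds")
})

test_that("feature images have the published geometry and metadata", {
  set.seed(8)
  mag <- matrix(stats::runif(64 * 7680), 64, 7680)  # 12 s at 640/s
  spec <- fake_spectrogram(mag)
  imgs <- extract_feature_images(spec, feature_params(), posture = "prone",
                                 subject_id = "S9")
  expect_length(imgs, 2L)                       # two complete 6 s spans
  expect_identical(dim(imgs[[1L]]$values), c(40L, 60L))
  expect_equal(imgs[[1L]]$label, c(0, 0, 1), ignore_attr = TRUE)
  expect_identical(imgs[[1L]]$subject_id, "S9")
  expect_true(all(imgs[[1L]]$values >= 0))
  expect_error(extract_feature_images(fake_spectrogram(mag[, 1:100]),
                                      feature_params(), posture = "prone"),
               "shorter")
  zero <- extract_feature_images(fake_spectrogram(matrix(0, 64, 3840)),
                                 feature_params(), posture = "supine")
  expect_true(all(zero[[1L]]$values == 0))
  expect_identical(zero[[1L]]$bin_offset, 0L)   # tie-break at offset 0
})

test_that("features are scale-equivariant and the window is offset-invariant", {
  set.seed(9)
  mag <- matrix(stats::runif(64 * 3840), 64, 3840)
  p <- feature_params()
  a <- extract_feature_images(fake_spectrogram(mag), p, posture = "supine")[[1L]]
  b <- extract_feature_images(fake_spectrogram(3.5 * mag), p,
                              posture = "supine")[[1L]]
  expect_equal(b$values, 3.5 * a$values, tolerance = 1e-9)
  expect_identical(a$bin_offset, b$bin_offset)
})

test_that("the selected bin window dominates any disjoint window", {
  set.seed(10)
  stdmat <- matrix(stats::rexp(64 * 60), 64, 60)
  k1 <- 20L
  off <- select_bin_window(stdmat, k1)
  best <- sum(stdmat[(off + 1L):(off + k1), ])
  for (o in seq(0L, 64L - k1, by = k1)) {
    expect_lte(sum(stdmat[(o + 1L):(o + k1), ]), best)
  }
})

test_that("supine scenes yield larger mean features than lateral at equal gain", {
  ## paired scenes (same distance, gain, noise and seed) drawn from the two
  ## presets, 20 seeded repetitions; the comparison is on the repetition
  ## average because the slow-time mean-subtraction residual (proportional
  ## to J0(4 pi A_r / lambda)) makes single pairs non-monotone near the
  ## Bessel extrema
  p <- posture_presets()
  diffs <- vapply(1:20, function(r) {
    base <- withr::with_seed(100 + r, list(
      d = stats::runif(1, 0.6, 1.2),
      sup_ar = stats::runif(1, p$a_r_min[1], p$a_r_max[1]),
      sup_sp = sample(p$spread_min[1]:p$spread_max[1], 1),
      lat_ar = stats::runif(1, p$a_r_min[2], p$a_r_max[2]),
      lat_sp = sample(p$spread_min[2]:p$spread_max[2], 1)))
    mk <- function(ar, sp) {
      sc <- scene_config(torso_distance_m = base$d, respiration_amplitude_m = ar,
                         motion_spread_bins = sp, noise_sigma = 0.1,
                         seed = 200 + r)
      cube <- synthesize_cube(sc, default_cfg, 6)
      img <- extract_feature_images(range_fft(preprocess_cube(cube)),
                                    feature_params(), posture = "supine")[[1L]]
      mean(img$values)
    }
    mk(base$sup_ar, base$sup_sp) - mk(base$lat_ar, base$lat_sp)
  }, 0)
  expect_gt(mean(diffs), 0)
  expect_gt(stats::median(diffs), 0)
  expect_gt(mean(diffs > 0), 0.8)
})

test_that("raw range-FFT images are snapshot columns of the same geometry", {
  set.seed(11)
  mag <- matrix(stats::runif(64 * 3840), 64, 3840)
  imgs <- extract_rawfft_images(fake_spectrogram(mag), feature_params(),
                                posture = "supine")
  expect_length(imgs, 1L)
  expect_identical(dim(imgs[[1L]]$values), c(40L, 60L))
  ## each column is one chirp's magnitudes (no temporal statistic computed)
  off <- imgs[[1L]]$bin_offset
  cols <- seq.int(64L %/% 2L, 60L * 64L, by = 64L)[1:60]
  expect_identical(imgs[[1L]]$values,
                   mag[(off + 1L):(off + 40L), cols])
})

test_that("feature sets round-trip through persistence", {
  imgs <- list(toy_image(8L, 6L), toy_image(8L, 6L, posture = "prone", seed = 2L))
  path <- withr::local_tempfile(fileext = ".rds")
  write_feature_set(imgs, path)
  expect_equal(read_feature_set(path), imgs)
})
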