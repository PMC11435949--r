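test_that("time shift rotates columns circularly and validates the offset", {
  img <- toy_image(10L, 20L)
  expect_equal(time_shift(img, 0)$values, img$values)
  expect_equal(time_shift(time_shift(img, 1), -1)$values, img$values)
  shifted <- time_shift(img, 0.3)               # 3 columns
  expect_equal(shifted$values[, 4:20], img$values[, 1:17])
  expect_equal(shifted$values[, 1:3], img$values[, 18:20])
  expect_equal(shifted$label, img$label)
  expect_error(time_shift(img, 0.17), "whole number")
})

test_that("range shift zero-fills vacated bins", {
  img <- toy_image(40L, 6L)
  expect_equal(range_shift(img, 0L)$values, img$values)
  up <- range_shift(img, 10L)
  expect_true(all(up$values[1:10, ] == 0))
  expect_equal(up$values[11:40, ], img$values[1:30, ])
  down <- range_shift(img, -10L)
  expect_true(all(down$values[31:40, ] == 0))
  expect_equal(down$values[1:30, ], img$values[11:40, ])
  expect_error(range_shift(img, 40L), ">= image height")
})

test_that("mix-up forms convex combinations of images and labels", {
  a <- toy_image(8L, 5L, posture = "supine", seed = 1L)
  b <- toy_image(8L, 5L, posture = "prone", seed = 2L)
  expect_equal(mixup(a, b, 1)$values, a$values)
  expect_equal(mixup(a, b, 1)$label, a$label)
  half <- mixup(a, b, 0.5)
  expect_equal(half$label, c(0.5, 0, 0.5), ignore_attr = TRUE)
  for (lam in c(0, 0.3, 0.8)) {
    m <- mixup(a, b, lam)$values
    expect_true(all(m >= pmin(a$values, b$values) - 1e-12))
    expect_true(all(m <= pmax(a$values, b$values) + 1e-12))
    expect_equal(sum(mixup(a, b, lam)$label), 1)
  }
  small <- toy_image(4L, 5L, posture = "prone")
  expect_error(mixup(a, small, 0.5), "shape mismatch")
})

test_that("sampled shift offsets stay inside the published intervals", {
  draws <- withr::with_seed(13, {
    t_draws <- replicate(1000, radarposture:::sample_signed(c(5L, 10L), TRUE))
    r_draws <- replicate(1000, radarposture:::sample_signed(c(5L, 10L), TRUE))
    list(t = t_draws, r = r_draws)
  })
  ## time: [-1,-0.5] or [0.5,1] s maps to -10..-5 or 5..10 columns of 0.1 s
  expect_true(all(abs(draws$t) >= 5 & abs(draws$t) <= 10))
  expect_true(all(abs(draws$r) >= 5 & abs(draws$r) <= 10))
  expect_true(any(draws$t < 0) && any(draws$t > 0))
})

test_that("dataset augmentation is seeded, labelled and provenance-tracked", {
  imgs <- c(lapply(1:4, function(i) toy_image(12L, 20L, "supine", i, sprintf("A%d", i))),
            lapply(1:4, function(i) toy_image(12L, 20L, "prone", 10 + i, sprintf("B%d", i))))
  cfg <- augment_config(multiplicity = 1L, seed = 42L)
  out1 <- augment_dataset(imgs, cfg)
  out2 <- augment_dataset(imgs, cfg)
  expect_length(out1, 8L * 4L)                  # originals + 3 per image
  expect_identical(lapply(out1, function(x) x$values),
                   lapply(out2, function(x) x$values))
  expect_identical(augment_dataset(imgs, augment_config(multiplicity = 0L)),
                   imgs)
  aug <- out1[-(1:8)]
  for (im in aug) {
    expect_true(all(im$values >= 0))
    expect_gte(min(im$label), 0)
    expect_equal(sum(im$label), 1)
  }
  prov <- lapply(aug, attr, "augmented")
  expect_setequal(unique(vapply(prov, `[[`, "", "op")),
                  c("time_shift", "range_shift", "mixup"))
  ## mix-up always pairs different classes
  mixes <- prov[vapply(prov, `[[`, "", "op") == "mixup"]
  for (mp in mixes) {
    cls <- vapply(imgs[mp$source], function(im) which.max(im$label), 1L)
    expect_length(unique(cls), 2L)
  }
})

test_that("mix-up weights follow the symmetric Beta(0.4, 0.4) law", {
  imgs <- c(lapply(1:50, function(i) toy_image(6L, 8L, "supine", i)),
            lapply(1:50, function(i) toy_image(6L, 8L, "prone", 100 + i)))
  cfg <- augment_config(multiplicity = 1L, use_time_shift = FALSE,
                        use_range_shift = FALSE, seed = 7L)
  out <- augment_dataset(imgs, cfg)
  lam <- vapply(out[-(1:100)], function(im) attr(im, "augmented")$lambda, 0)
  expect_gte(length(lam), 100L)
  expect_lt(abs(mean(lam) - 0.5), 0.1)
})

test_that("single-class input cannot be mixed up", {
  imgs <- lapply(1:3, function(i) toy_image(16L, 8L, "supine", i))
  expect_error(augment_dataset(imgs, augment_config()), "two classes")
  ## but shifts alone are fine
  cfg <- augment_config(use_mixup = FALSE)
  expect_length(augment_dataset(imgs, cfg), 9L)
})
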