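test_that("chest displacement follows the two-tone model", {
  t <- seq(0, 10, by = 0.05)
  sc <- quiet_scene(distance = 0.8)
  expect_equal(chest_displacement(sc, t), rep(0.8, length(t)))
  sc2 <- quiet_scene(distance = 0.8, a_r = 6e-3, a_h = 4e-4)
  d <- chest_displacement(sc2, t)
  expect_true(all(abs(d - 0.8) <= 6e-3 + 4e-4 + 1e-12))
})

test_that("the displacement spectrum peaks at the breathing rate", {
  t <- seq(0, 60, by = 0.05)
  sc <- quiet_scene(a_r = 8e-3, a_h = 1e-4, f_r = 0.3)
  d <- chest_displacement(sc, t)
  sp <- Mod(stats::fft(d - mean(d)))[2:(length(t) %/% 2)]
  f <- (2:(length(t) %/% 2) - 1) / 60
  expect_equal(f[which.max(sp)], 0.3, tolerance = 0.05)
})

test_that("a silent scene synthesises an all-zero cube", {
  sc <- quiet_scene()
  sc$reflector_amplitude <- 0
  cube <- synthesize_cube(sc, default_cfg, duration_s = 1)
  expect_true(all(cube$samples == 0))
  expect_identical(dim(cube$samples), c(128L, 640L))
})

test_that("static targets land on the predicted beat bin", {
  for (D in c(0.4, 0.6, 0.8, 1.0, 1.4)) {
    cube <- synthesize_cube(quiet_scene(distance = D), default_cfg, 1)
    spec <- range_fft(cube$samples, default_cfg)
    expect_identical(which.max(rowMeans(spec$magnitude)) - 1L,
                     beat_bin(D, default_cfg))
  }
})

test_that("scenes beyond the unambiguous range are rejected", {
  expect_error(synthesize_cube(quiet_scene(distance = 2.5), default_cfg, 1),
               "unambiguous")
})

test_that("torso-bin amplitude is invariant to the drawn phases when static", {
  mags <- sapply(c(11L, 12L), function(s) {
    cube <- synthesize_cube(quiet_scene(distance = 0.7, seed = s),
                            default_cfg, 1)
    max(rowMeans(range_fft(cube$samples, default_cfg)$magnitude))
  })
  expect_equal(mags[1L], mags[2L], tolerance = 1e-9)
})

test_that("cube synthesis is deterministic in the scene seed", {
  sc <- quiet_scene(a_r = 5e-3, noise = 0.2, seed = 9L)
  c1 <- synthesize_cube(sc, default_cfg, 1)
  c2 <- synthesize_cube(sc, default_cfg, 1)
  expect_identical(c1$samples, c2$samples)
})

test_that("posture presets are monotone and separable by construction", {
  p <- posture_presets()
  sup <- p[p$posture == "supine", ]
  lat <- p[p$posture == "left_lateral", ]
  pro <- p[p$posture == "prone", ]
  expect_gt(sup$a_r_min, lat$a_r_max)           # amplitude ranges disjoint
  expect_gt(sup$spread_min, lat$spread_max)     # spread ranges disjoint
  expect_lt(pro$amp_factor, sup$amp_factor)     # prone return damped
  expect_identical(p$posture, POSTURES4)
})

test_that("the dataset generator is reproducible and correctly sized", {
  cubes <- make_dataset(posture_presets(), n_subjects = 4L,
                        minutes_per_posture = 0.05, default_cfg, seed = 2L)
  expect_length(cubes, 16L)                     # 4 subjects x 4 postures
  man <- attr(cubes, "manifest")
  expect_identical(sort(unique(man$subject_id)),
                   sprintf("S%02d", 1:4))
  expect_identical(sort(unique(man$class3)), c(0L, 1L, 2L))
  cubes2 <- make_dataset(posture_presets(), n_subjects = 4L,
                         minutes_per_posture = 0.05, default_cfg, seed = 2L)
  expect_identical(cubes[[7L]]$samples, cubes2[[7L]]$samples)
  expect_error(dataset_scenes(posture_presets()[0, ], 4L, default_cfg),
               "empty")
  expect_error(dataset_scenes(posture_presets(), 2L, default_cfg))
})

test_that("study-scale arithmetic: 16 subjects x 4 postures x 10 min", {
  plan <- dataset_scenes(posture_presets(), 16L, default_cfg, seed = 1L)
  expect_identical(nrow(plan), 64L)
  expect_identical(nrow(plan) * 10, 640)        # total acquisition minutes
})
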