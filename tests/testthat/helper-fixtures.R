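## Shared fixtures: everything is generated in code at test time.

default_cfg <- radar_config()

## a quiet single-reflector scene for physics checks
quiet_scene <- function(distance = 0.6, a_r = 0, a_h = 0, spread = 1L,
                        noise = 0, dc = 0, clutter = list(), seed = 3L,
                        f_r = 0.3, bin_locked = FALSE) {
  scene_config(torso_distance_m = distance,
               respiration_rate_hz = f_r,
               respiration_amplitude_m = a_r,
               heartbeat_rate_hz = 1.1,
               heartbeat_amplitude_m = a_h,
               motion_spread_bins = spread,
               reflector_amplitude = 1,
               clutter = clutter,
               dc_offset = dc,
               noise_sigma = noise,
               bin_locked = bin_locked,
               seed = seed)
}

## a deterministic non-negative feature image for augmentation tests
toy_image <- function(nr = 40L, nc = 60L, posture = "supine", seed = 1L,
                      subject = "S0") {
  v <- withr::with_seed(seed, matrix(stats::runif(nr * nc), nr, nc))
  motion_feature_image(v, bin_offset = 0L, label = posture_onehot(posture),
                       subject_id = subject, posture = posture)
}

## brute-force per-window two-pass standard deviation (independent oracle)
naive_sliding_std <- function(mag, W, S) {
  N <- ncol(mag)
  nw <- N %/% S
  magp <- cbind(mag, mag[, rep(N, W - S), drop = FALSE])
  vapply(seq_len(nw) - 1L, function(i) {
    win <- magp[, (i * S + 1L):(i * S + W), drop = FALSE]
    apply(win, 1L, function(v) sqrt(mean((v - mean(v))^2)))
  }, numeric(nrow(mag)))
}

## exhaustive bin-window search (independent oracle)
naive_select_bin_window <- function(stdmat, k1) {
  K <- nrow(stdmat)
  sums <- vapply(0:(K - k1), function(o) {
    sum(stdmat[(o + 1L):(o + k1), ])
  }, 0)
  which.max(sums) - 1L
}

## minimal model/training configs for fast tests
tiny_model_cfg <- function(seed = 7L, dropout = 0) {
  model_config(stage_channels = c(4L, 8L), embedding_dim = 16L,
               tcn_channels = c(8L, 8L), tcn_dilations = c(1L, 2L),
               dropout = dropout, temporal_pool = 2L, seed = seed)
}

## small labelled image set with class-dependent structure: class k lights a
## distinct row band, brightness varies per image
toy_labelled_images <- function(n_per_class = 3L, nr = 24L, nc = 16L,
                                seed = 11L) {
  withr::with_seed(seed, {
    out <- list()
    for (k in 0:2) {
      for (i in seq_len(n_per_class)) {
        v <- matrix(stats::runif(nr * nc, 0, 0.1), nr, nc)
        rows <- (k * 7 + 2):(k * 7 + 6)
        v[rows, ] <- v[rows, ] + stats::runif(1, 0.8, 1.2)
        out[[length(out) + 1L]] <- motion_feature_image(
          v, bin_offset = 0L, label = posture_onehot(POSTURES4[k + 1L]),
          subject_id = sprintf("T%d", i), posture = POSTURES4[k + 1L])
      }
    }
    out
  })
}

## fake spectrogram wrapper for feature tests that need no radar simulation
fake_spectrogram <- function(mag, rate = 640) {
  structure(list(values = mag + 0i, magnitude = mag, bin_pitch_m = 0.04,
                 slow_time_rate_hz = rate, config = NULL),
            class = "range_spectrogram")
}
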