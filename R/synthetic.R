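#' Synthetic bed-scene configuration
#'
#' Describes one simulated recording: a dominant torso reflector at distance
#' `torso_distance_m` whose range is modulated by quasi-periodic chest
#' displacement (respiration plus heartbeat), optional adjacent sub-reflectors
#' that smear the motion energy over neighbouring range bins, static clutter
#' reflectors, a DC offset and additive Gaussian noise. The sinusoid phases of
#' the two physiological components are drawn once from the scene seed, so a
#' scene is a fully deterministic description.
#'
#' @param torso_distance_m Torso standoff D (m); typical bed geometry 0.6-1.2.
#' @param respiration_rate_hz Breathing rate f_r (Hz); adults at rest 0.2-0.4.
#' @param respiration_amplitude_m Chest-wall breathing excursion A_r (m),
#'   1-12 mm depending on posture.
#' @param heartbeat_rate_hz Heartbeat rate f_h (Hz).
#' @param heartbeat_amplitude_m Heartbeat surface amplitude A_h (m), 0.1-0.5 mm.
#' @param motion_spread_bins Number of adjacent range bins carrying correlated
#'   motion energy (>= 1); sub-reflectors are placed one FFT-bin spacing apart
#'   with geometrically decaying weights.
#' @param reflector_amplitude Dimensionless IF amplitude A of the torso return.
#' @param clutter List of static reflectors, each `list(distance_m=, amplitude=)`.
#' @param dc_offset Constant additive offset on every IF sample.
#' @param noise_sigma Standard deviation of i.i.d. Gaussian sample noise.
#' @param bin_locked If TRUE (default), the torso scatterer profile is
#'   snapped to a fixed quarter-bin offset from the nearest range-bin
#'   centres, so every scene has an identical array response and feature
#'   statistics depend only on the physiological parameters; FALSE places
#'   the scatterers exactly at the programmed distance (used for analytic
#'   identities).
#' @param seed Integer seed controlling phases and noise.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(torso_distance_m = 0.9,
                         respiration_rate_hz = 0.3,
                         respiration_amplitude_m = 6e-3,
                         heartbeat_rate_hz = 1.1,
                         heartbeat_amplitude_m = 3e-4,
                         motion_spread_bins = 3L,
                         reflector_amplitude = 1.0,
                         clutter = list(),
                         dc_offset = 0.2,
                         noise_sigma = 0.1,
                         bin_locked = TRUE,
                         seed = 1L) {
  stopifnot(torso_distance_m > 0,
            respiration_rate_hz > 0, heartbeat_rate_hz > 0,
            respiration_amplitude_m >= 0, heartbeat_amplitude_m >= 0,
            motion_spread_bins >= 1L, reflector_amplitude >= 0,
            noise_sigma >= 0)
  phases <- withr::with_seed(as.integer(seed), stats::runif(2L, 0, 2 * pi))
  structure(
    list(torso_distance_m = torso_distance_m,
         respiration_rate_hz = respiration_rate_hz,
         respiration_amplitude_m = respiration_amplitude_m,
         heartbeat_rate_hz = heartbeat_rate_hz,
         heartbeat_amplitude_m = heartbeat_amplitude_m,
         motion_spread_bins = as.integer(motion_spread_bins),
         reflector_amplitude = reflector_amplitude,
         clutter = clutter,
         dc_offset = dc_offset,
         noise_sigma = noise_sigma,
         bin_locked = isTRUE(bin_locked),
         seed = as.integer(seed),
         phase_respiration = phases[1L],
         phase_heartbeat = phases[2L]),
    class = "scene_config"
  )
}

#' Chest displacement time series of a scene
#'
#' d(t) = D + A_r sin(2 pi f_r t + phi_r) + A_h sin(2 pi f_h t + phi_h),
#' the two phases having been drawn from the scene seed at construction.
#'
#' @param scene A [scene_config()].
#' @param t Non-empty, monotone non-decreasing time vector (s).
#' @return Numeric vector of radar-to-chest distances (m), same length as `t`.
#' @export
chest_displacement <- function(scene, t) {
  stopifnot(inherits(scene, "scene_config"), length(t) > 0, !is.unsorted(t))
  scene$torso_distance_m +
    scene$respiration_amplitude_m *
      sin(2 * pi * scene$respiration_rate_hz * t + scene$phase_respiration) +
    scene$heartbeat_amplitude_m *
      sin(2 * pi * scene$heartbeat_rate_hz * t + scene$phase_heartbeat)
}

#' Chirp start times over a recording
#'
#' Chirps are spaced `chirp_repetition_s` apart within a frame; frames repeat
#' at the frame rate, the remainder of each frame period being dead time.
#'
#' @param config A [radar_config()].
#' @param duration_s Recording length (s); must hold a whole number of frames.
#' @return Numeric vector of chirp start times (s).
#' @export
chirp_times <- function(config, duration_s) {
  n_frames <- round(duration_s * config$frame_rate_hz)
  stopifnot(n_frames >= 1)
  frame_starts <- (seq_len(n_frames) - 1L) / config$frame_rate_hz
  within <- (seq_len(config$chirps_per_frame) - 1L) * config$chirp_repetition_s
  rep(frame_starts, each = config$chirps_per_frame) +
    rep(within, times = n_frames)
}

## Distance spanned by one fast-time DFT bin: a beat tone advances one bin per
## adc_rate/M of beat frequency, i.e. c/(2 s M Ts) metres.
fft_bin_spacing_m <- function(config) {
  d <- derived_params(config)
  C_LIGHT * config$adc_rate_hz / (2 * d$slope_hz_per_s * config$samples_per_chirp)
}

#' Predicted range-FFT peak bin for a static target
#'
#' The IF beat frequency of a target at distance D is f0 = 2 D s / c; after an
#' M-point DFT of samples taken at interval Ts it lands on bin
#' round(f0 M Ts) (0-based).
#'
#' @param distance_m Target distance (m).
#' @param config A [radar_config()].
#' @return Integer 0-based bin index.
#' @export
beat_bin <- function(distance_m, config) {
  d <- derived_params(config)
  f0 <- d$slope_hz_per_s * 2 * distance_m / C_LIGHT
  as.integer(round(f0 * config$samples_per_chirp / config$adc_rate_hz))
}

## Rigid torso scatterer profile: per spread bin j (centred offsets
## 0, +1, -1, ...) one scatterer of amplitude A * 0.75^|j|. Offsets are
## relative to the programmed distance D; when the scene is bin-locked the
## whole profile is shifted so each scatterer sits a quarter bin above its
## bin centre, standardising the DFT array response across scenes.
torso_scatterers <- function(scene, config) {
  k_spread <- scene$motion_spread_bins
  offs <- seq_len(k_spread) - ceiling(k_spread / 2)
  offs <- offs[order(abs(offs), offs)]
  w <- scene$reflector_amplitude * 0.75^abs(offs)
  pitch <- fft_bin_spacing_m(config)
  delta <- offs * pitch
  if (scene$bin_locked) {
    k0 <- round(scene$torso_distance_m / pitch)
    delta <- (k0 + offs + 0.25) * pitch - scene$torso_distance_m
  }
  list(delta = delta, amp = w)
}

## Adds one sinusoidal IF return to `acc` in place-ish (returns the sum).
## dist: per-chirp distance vector (length N). IF tone per chirp:
## x_m = A sin(2 pi f0 Ts m + phi0), m = 1..M, f0 = 2 d s / c, phi0 = 4 pi d / lambda.
add_reflector <- function(acc, dist, amplitude, config) {
  d <- derived_params(config)
  Ts <- 1 / config$adc_rate_hz
  f0 <- d$slope_hz_per_s * 2 * dist / C_LIGHT
  phi0 <- 4 * pi * dist / d$wavelength_m
  m <- seq_len(config$samples_per_chirp)
  ph <- outer(2 * pi * Ts * m, f0)
  ph <- ph + rep(phi0, each = config$samples_per_chirp)
  acc + amplitude * sin(ph)
}

#' Synthesise a raw IF cube for one scene
#'
#' Each chirp is treated as quasi-static: the torso distance is frozen at the
#' chirp start time, so fast-time samples follow the sinusoidal IF model with
#' the beat frequency and phase set by the instantaneous chest distance. The
#' torso return is a rigid, co-moving profile of scatterers spanning
#' `motion_spread_bins` range bins (geometrically decaying per-bin
#' amplitudes; a wider moving surface returns more total energy), optionally
#' bin-locked so the array response is identical across scenes. The sub-bin
#' translation of this profile under breathing is what the motion-feature
#' statistic measures. Because all torso scatterers share the same motion,
#' the profile is synthesised with a single complex exponential regardless
#' of scatterer count. Static clutter and a DC offset are added as further
#' static terms, then i.i.d. Gaussian noise.
#'
#' @param scene A [scene_config()].
#' @param config A [radar_config()].
#' @param duration_s Recording length (s), >= 1 frame; >= 1 s for downstream
#'   feature extraction.
#' @param subject_id,posture,start_time_s Metadata stored on the cube.
#' @return A [raw_cube()].
#' @export
synthesize_cube <- function(scene, config, duration_s,
                            subject_id = "S0", posture = "supine",
                            start_time_s = 0) {
  stopifnot(inherits(scene, "scene_config"), inherits(config, "radar_config"))
  dp <- derived_params(config)
  ## beat frequency must stay below ADC Nyquist (and inside the one-sided FFT)
  max_d <- C_LIGHT * config$adc_rate_hz / (4 * dp$slope_hz_per_s)
  if (scene$torso_distance_m >= max_d) {
    stop(sprintf("scene distance %.2f m outside unambiguous range (< %.2f m)",
                 scene$torso_distance_m, max_d), call. = FALSE)
  }
  t_n <- chirp_times(config, duration_s) + start_time_s
  N <- length(t_n)
  M <- config$samples_per_chirp
  d_t <- chest_displacement(scene, t_n)

  X <- matrix(0, M, N)
  if (scene$reflector_amplitude > 0) {
    sc <- torso_scatterers(scene, config)
    ## all torso scatterers co-move with d(t): the IF sum is
    ## Im(exp(i P(m, n)) * W(m)) with P the phase of a scatterer at d(t) and
    ## W the fixed complex array factor of the profile offsets
    Ts <- 1 / config$adc_rate_hz
    k_m <- 2 * pi * dp$slope_hz_per_s * 2 * Ts / C_LIGHT   # rad per m per sample
    k_0 <- 4 * pi / dp$wavelength_m                        # rad per m
    m <- seq_len(M)
    U <- exp(1i * (outer(m, k_m * d_t) + rep(k_0 * d_t, each = M)))
    W <- as.vector(exp(1i * (outer(m, k_m * sc$delta) +
                             rep(k_0 * sc$delta, each = M))) %*% sc$amp)
    X <- X + Im(U * W)
  }
  for (cl in scene$clutter) {
    X <- add_reflector(X, rep(cl$distance_m, N), cl$amplitude, config)
  }
  X <- X + scene$dc_offset
  if (scene$noise_sigma > 0) {
    X <- X + withr::with_seed(
      scene$seed + 1L,
      matrix(stats::rnorm(M * N, sd = scene$noise_sigma), M, N)
    )
  }
  raw_cube(X, config, subject_id = subject_id, posture = posture,
           start_time_s = start_time_s)
}

#' Posture presets for the synthetic generator
#'
#' Parameter ranges emulating posture-dependent motion signatures: supine
#' exposes the full chest to the radar (large breathing amplitude, wide
#' spatial spread), lateral postures present the side of the ribcage (small
#' amplitude, narrow spread), prone is intermediate with a damped return.
#'
#' @return A tibble with one row per acquisition posture: breathing-amplitude
#'   range (m), motion-spread range (bins) and a reflector amplitude factor.
#' @export
posture_presets <- function() {
  tibble::tibble(
    posture = POSTURES4,
    a_r_min = c(6e-3, 1e-3, 1e-3, 3e-3),
    a_r_max = c(12e-3, 4e-3, 4e-3, 7e-3),
    spread_min = c(4L, 1L, 1L, 2L),
    spread_max = c(6L, 3L, 3L, 4L),
    amp_factor = c(1.0, 1.0, 1.0, 0.7)
  )
}

#' Scene plan for a multi-subject synthetic dataset
#'
#' Draws, reproducibly from `seed`, one scene per subject-posture pair:
#' subject-level parameters (torso distance, breathing and heart rates,
#' reflector gain, room clutter, DC offset) are drawn once per subject;
#' posture-level parameters (breathing amplitude, motion spread, amplitude
#' damping) come from the preset ranges.
#'
#' @param presets Preset tibble as from [posture_presets()].
#' @param n_subjects Number of subjects (>= 3 so a subject-wise split exists).
#' @param config A [radar_config()].
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `posture`, `class3` and a
#'   `scene` list-column of [scene_config()] objects.
#' @export
dataset_scenes <- function(presets, n_subjects, config, seed = 1L) {
  if (nrow(presets) == 0) stop("empty preset table", call. = FALSE)
  stopifnot(n_subjects >= 3)
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("S%02d", s)
      dist <- stats::runif(1, 0.6, 1.2)
      f_r <- stats::runif(1, 0.2, 0.4)
      f_h <- stats::runif(1, 0.9, 1.3)
      a_h <- stats::runif(1, 1e-4, 5e-4)
      gain <- stats::runif(1, 0.9, 1.1)
      dc <- stats::runif(1, 0.0, 0.4)
      clutter <- list(
        list(distance_m = stats::runif(1, 0.25, 0.55), amplitude = stats::runif(1, 0.2, 0.6)),
        list(distance_m = stats::runif(1, 1.3, 1.9), amplitude = stats::runif(1, 0.1, 0.4))
      )
      for (p in seq_len(nrow(presets))) {
        pr <- presets[p, ]
        sc <- scene_config(
          torso_distance_m = dist + stats::runif(1, -0.03, 0.03),
          respiration_rate_hz = f_r,
          respiration_amplitude_m = stats::runif(1, pr$a_r_min, pr$a_r_max),
          heartbeat_rate_hz = f_h,
          heartbeat_amplitude_m = a_h,
          motion_spread_bins = sample(pr$spread_min:pr$spread_max, 1L),
          reflector_amplitude = gain * pr$amp_factor,
          clutter = clutter,
          dc_offset = dc,
          noise_sigma = 0.1,
          seed = sample.int(2147483646L, 1L)
        )
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject_id = sid, posture = pr$posture,
          class3 = map_to_3class(pr$posture)[1L], scene = list(sc)
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a labelled synthetic dataset of raw cubes
#'
#' One cube per subject-posture pair, fully reproducible from `seed`. The
#' study design this emulates is N subjects x 4 postures x a fixed recording
#' time per posture.
#'
#' @inheritParams dataset_scenes
#' @param minutes_per_posture Recording length per posture (min).
#' @return A list of [raw_cube()] objects with a `manifest` attribute (tibble
#'   of subject, posture and class).
#' @export
make_dataset <- function(presets, n_subjects, minutes_per_posture, config,
                         seed = 1L) {
  plan <- dataset_scenes(presets, n_subjects, config, seed = seed)
  cubes <- lapply(seq_len(nrow(plan)), function(i) {
    synthesize_cube(plan$scene[[i]], config,
                    duration_s = minutes_per_posture * 60,
                    subject_id = plan$subject_id[i],
                    posture = plan$posture[i])
  })
  attr(cubes, "manifest") <- plan[, c("subject_id", "posture", "class3")]
  cubes
}
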