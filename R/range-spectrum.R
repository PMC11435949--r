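#' Range Fourier transform of a preprocessed cube
#'
#' Applies an M-point DFT to the fast-time samples of every chirp (no
#' windowing, no zero padding) and keeps the one-sided spectrum, bins 0 to
#' K-1 with K = M/2. Each retained bin is a range shell; the magnitude over
#' slow time is the range spectrogram used downstream.
#'
#' @param clean A `clean_cube` from [preprocess_cube()], or a plain numeric
#'   matrix (fast time x slow time).
#' @param config Radar configuration; taken from the clean cube's provenance
#'   when omitted. Needed only for physical annotations (bin pitch, slow-time
#'   rate).
#' @return A `range_spectrogram`: list with complex `values` (K x N),
#'   `magnitude` (K x N), `bin_pitch_m`, `slow_time_rate_hz`, `config`.
#' @export
range_fft <- function(clean, config = NULL) {
  Y <- if (inherits(clean, "clean_cube")) clean$samples else clean
  stopifnot(is.matrix(Y))
  if (is.null(config) && inherits(clean, "clean_cube") &&
      inherits(clean$provenance, "raw_cube")) {
    config <- clean$provenance$config
  }
  M <- nrow(Y)
  if (M %% 2L != 0L) stop("fast-time length M must be even", call. = FALSE)
  K <- M %/% 2L
  vals <- stats::mvfft(Y)[seq_len(K), , drop = FALSE]
  structure(
    list(values = vals,
         magnitude = Mod(vals),
         bin_pitch_m = if (!is.null(config)) config$bin_pitch_m else NA_real_,
         slow_time_rate_hz = if (!is.null(config))
           derived_params(config)$chirps_per_second else NA_real_,
         config = config),
    class = "range_spectrogram"
  )
}

#' @export
print.range_spectrogram <- function(x, ...) {
  cat(sprintf("<range_spectrogram> %d bins x %d chirps\n",
              nrow(x$magnitude), ncol(x$magnitude)))
  invisible(x)
}

#' Range bin of the dominant (torso) return
#'
#' The bin with the largest mean magnitude over slow time. After
#' preprocessing, static returns are suppressed, so this is the strongest
#' moving reflector - for a bed scene, the torso - and the bin whose phase
#' can be demodulated without passing near magnitude nulls.
#'
#' @param spectrogram A `range_spectrogram`.
#' @return Integer 0-based bin index.
#' @export
torso_bin <- function(spectrogram) {
  as.integer(which.max(rowMeans(spectrogram$magnitude)) - 1L)
}

#' Unwrap a phase sequence
#'
#' Removes 2*pi jumps so the phase evolves continuously.
#'
#' @param p Numeric vector of wrapped phases (rad).
#' @return Numeric vector of unwrapped phases.
#' @export
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  p[1L] + c(0, cumsum(dp))
}

#' Slow-time phase at a range bin
#'
#' Unwrapped argument of the complex spectrogram at one bin; for the torso
#' bin this tracks the chest displacement (4 pi d(t) / lambda up to an
#' offset).
#'
#' @param spectrogram A `range_spectrogram`.
#' @param bin 0-based bin index; defaults to [torso_bin()].
#' @return Numeric vector of unwrapped phases (rad), one per chirp.
#' @export
bin_phase <- function(spectrogram, bin = torso_bin(spectrogram)) {
  unwrap_phase(Arg(spectrogram$values[bin + 1L, ]))
}

#' Estimate the breathing rate from a range spectrogram
#'
#' Demodulates the unwrapped phase at the torso bin, samples it once per
#' frame (frames are uniformly spaced; chirps within a frame are not, because
#' of inter-frame dead time), and locates the dominant peak of its spectrum
#' in the physiological band with parabolic interpolation.
#'
#' @param spectrogram A `range_spectrogram` with an attached config.
#' @param band Frequency band searched (Hz).
#' @return Estimated rate (Hz).
#' @export
estimate_breathing_rate <- function(spectrogram, band = c(0.1, 0.6)) {
  cfg <- spectrogram$config
  stopifnot(!is.null(cfg))
  ph <- bin_phase(spectrogram)
  ## one chirp per frame -> uniform sampling at the frame rate
  ph <- ph[seq(1L, length(ph), by = cfg$chirps_per_frame)]
  fs <- cfg$frame_rate_hz
  n <- length(ph)
  ph <- ph - mean(ph)
  hann <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1L) / (n - 1L)))
  spec <- Mod(stats::fft(ph * hann))[seq_len(n %/% 2L)]
  freqs <- (seq_len(n %/% 2L) - 1L) * fs / n
  in_band <- which(freqs >= band[1L] & freqs <= band[2L])
  pk <- in_band[which.max(spec[in_band])]
  ## parabolic interpolation on log magnitude
  if (pk > 1L && pk < length(spec)) {
    a <- log(spec[pk - 1L] + 1e-300)
    b <- log(spec[pk] + 1e-300)
    cc <- log(spec[pk + 1L] + 1e-300)
    denom <- a - 2 * b + cc
    delta <- if (abs(denom) > 1e-12) 0.5 * (a - cc) / denom else 0
  } else {
    delta <- 0
  }
  (pk - 1L + delta) * fs / n
}

#' @method autoplot range_spectrogram
#' @export
autoplot.range_spectrogram <- function(object, max_cols = 640L, ...) {
  mag <- object$magnitude
  if (ncol(mag) > max_cols) {
    mag <- mag[, round(seq(1L, ncol(mag), length.out = max_cols)), drop = FALSE]
  }
  df <- expand.grid(bin = seq_len(nrow(mag)) - 1L, chirp = seq_len(ncol(mag)))
  df$magnitude <- as.vector(mag)
  ggplot2::ggplot(df, ggplot2::aes(.data$chirp, .data$bin,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "slow time (chirp)", y = "range bin",
                  fill = "|F|") +
    ggplot2::theme_minimal()
}
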