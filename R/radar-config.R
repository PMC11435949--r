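#' @keywords internal
#' @useDynLib radarposture, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

## Speed of light in vacuum (m/s). Printed "3 cm" resolutions are rounded
## display values; all physics here uses the exact constant.
C_LIGHT <- 2.99792458e8

#' FMCW radar acquisition parameters
#'
#' Bundles the transmit/sampling parameters of a linear-chirp FMCW radar
#' together with the bin pitch used for physical-span reporting. Defaults
#' reproduce a 58 GHz, 5 GHz-bandwidth single-antenna device: 128 ADC samples
#' per 133 us chirp at 1 MHz, 32 chirps per frame at 20 frames/s (640
#' chirps/s of slow time).
#'
#' @param bandwidth_hz Chirp sweep bandwidth B (Hz).
#' @param start_frequency_hz Chirp start frequency (Hz); sets the wavelength.
#' @param chirp_duration_s Active chirp (sweep) duration T_c (s).
#' @param chirp_repetition_s Chirp-to-chirp repetition interval within a
#'   frame (s); must be >= `chirp_duration_s`.
#' @param samples_per_chirp Fast-time samples M digitised per chirp.
#' @param chirps_per_frame Chirps in one frame.
#' @param frame_rate_hz Frame repetition rate (Hz).
#' @param adc_rate_hz ADC sampling rate 1/Ts (Hz).
#' @param bin_pitch_m Nominal per-bin range pitch (m) used when quoting the
#'   physical span of a bin window. Kept separate from the physical
#'   resolution c/(2B): devices commonly quote a coarser effective pitch
#'   (default 0.04 m, i.e. a 40-bin window spans 1.6 m).
#'
#' @return An object of class `radar_config`.
#' @seealso [derived_params()]
#' @export
#' @examples
#' cfg <- radar_config()
#' derived_params(cfg)
radar_config <- function(bandwidth_hz = 5.0e9,
                         start_frequency_hz = 58e9,
                         chirp_duration_s = 133e-6,
                         chirp_repetition_s = 463e-6,
                         samples_per_chirp = 128L,
                         chirps_per_frame = 32L,
                         frame_rate_hz = 20,
                         adc_rate_hz = 1e6,
                         bin_pitch_m = 0.04) {
  cfg <- structure(
    list(
      bandwidth_hz = as.numeric(bandwidth_hz),
      start_frequency_hz = as.numeric(start_frequency_hz),
      chirp_duration_s = as.numeric(chirp_duration_s),
      chirp_repetition_s = as.numeric(chirp_repetition_s),
      samples_per_chirp = as.integer(samples_per_chirp),
      chirps_per_frame = as.integer(chirps_per_frame),
      frame_rate_hz = as.numeric(frame_rate_hz),
      adc_rate_hz = as.numeric(adc_rate_hz),
      bin_pitch_m = as.numeric(bin_pitch_m)
    ),
    class = "radar_config"
  )
  validate_radar_config(cfg)
  cfg
}

validate_radar_config <- function(cfg) {
  num <- unlist(cfg[c("bandwidth_hz", "start_frequency_hz", "chirp_duration_s",
                      "chirp_repetition_s", "samples_per_chirp",
                      "chirps_per_frame", "frame_rate_hz", "adc_rate_hz",
                      "bin_pitch_m")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("invalid radar_config: all parameters must be finite and strictly positive",
         call. = FALSE)
  }
  if (cfg$samples_per_chirp / cfg$adc_rate_hz > cfg$chirp_duration_s + 1e-12) {
    stop("invalid radar_config: ADC window (samples_per_chirp/adc_rate_hz) ",
         "does not fit inside one chirp", call. = FALSE)
  }
  if (cfg$chirp_repetition_s < cfg$chirp_duration_s) {
    stop("invalid radar_config: chirp_repetition_s < chirp_duration_s", call. = FALSE)
  }
  invisible(cfg)
}

#' Quantities derived from the radar parameters
#'
#' Pure function of a [radar_config()]: chirp slope s = B/T_c, wavelength
#' lambda = c/f_start, physical range resolution c/(2B), and the slow-time
#' sampling rate chirps_per_frame x frame_rate.
#'
#' @param config A `radar_config`.
#' @return A list with elements `slope_hz_per_s`, `wavelength_m`,
#'   `range_resolution_m`, `chirps_per_second`, `samples_per_second_slow`.
#' @export
derived_params <- function(config) {
  stopifnot(inherits(config, "radar_config"))
  validate_radar_config(config)
  cps <- config$chirps_per_frame * config$frame_rate_hz
  list(
    slope_hz_per_s = config$bandwidth_hz / config$chirp_duration_s,
    wavelength_m = C_LIGHT / config$start_frequency_hz,
    range_resolution_m = C_LIGHT / (2 * config$bandwidth_hz),
    chirps_per_second = cps,
    samples_per_second_slow = cps
  )
}

#' @export
print.radar_config <- function(x, ...) {
  d <- derived_params(x)
  cat("<radar_config>\n")
  cat(sprintf("  bandwidth: %.2f GHz, start frequency: %.1f GHz\n",
              x$bandwidth_hz / 1e9, x$start_frequency_hz / 1e9))
  cat(sprintf("  chirp: %.0f us active / %.0f us repetition, %d samples @ %.2f MHz\n",
              x$chirp_duration_s * 1e6, x$chirp_repetition_s * 1e6,
              x$samples_per_chirp, x$adc_rate_hz / 1e6))
  cat(sprintf("  frames: %d chirps @ %.1f Hz -> %.0f chirps/s\n",
              x$chirps_per_frame, x$frame_rate_hz, d$chirps_per_second))
  cat(sprintf("  range resolution: %.3f cm, bin pitch: %.1f cm, wavelength: %.2f mm\n",
              d$range_resolution_m * 100, x$bin_pitch_m * 100,
              d$wavelength_m * 1000))
  invisible(x)
}

#' Serialise / restore a radar configuration as YAML
#'
#' @param config A `radar_config`.
#' @param path File path.
#' @return `read_radar_config()` returns a `radar_config`.
#' @export
write_radar_config <- function(config, path) {
  stopifnot(inherits(config, "radar_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_radar_config
#' @export
read_radar_config <- function(path) {
  do.call(radar_config, yaml::read_yaml(path))
}
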