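#' Acquisition posture labels
#'
#' Four postures are acquired; left and right lateral are merged into one
#' class for recognition, giving three classes: supine, lateral, prone.
#'
#' @export
POSTURES4 <- c("supine", "left_lateral", "right_lateral", "prone")

#' @rdname POSTURES4
#' @export
POSTURES3 <- c("supine", "lateral", "prone")

#' Raw IF data cube
#'
#' Container for the fast-time x slow-time matrix of real-valued
#' intermediate-frequency (IF) samples of one recording: column n holds the M
#' ADC samples of chirp n.
#'
#' @param samples Numeric matrix, `samples_per_chirp` rows x N columns, N a
#'   multiple of `chirps_per_frame`.
#' @param config The [radar_config()] the cube was acquired under.
#' @param subject_id Subject identifier (character scalar).
#' @param posture One of `r paste(POSTURES4, collapse = ", ")`.
#' @param start_time_s Recording start offset (s).
#' @return An object of class `raw_cube`.
#' @export
raw_cube <- function(samples, config, subject_id = "S0",
                     posture = "supine", start_time_s = 0) {
  stopifnot(inherits(config, "radar_config"), is.matrix(samples))
  posture <- match.arg(posture, POSTURES4)
  if (nrow(samples) != config$samples_per_chirp) {
    stop("raw_cube: row count ", nrow(samples),
         " != samples_per_chirp ", config$samples_per_chirp, call. = FALSE)
  }
  if (ncol(samples) %% config$chirps_per_frame != 0L) {
    stop("raw_cube: slow-time length must be a multiple of chirps_per_frame",
         call. = FALSE)
  }
  structure(
    list(samples = samples, config = config,
         subject_id = as.character(subject_id), posture = posture,
         start_time_s = as.numeric(start_time_s)),
    class = "raw_cube"
  )
}

#' @export
print.raw_cube <- function(x, ...) {
  cat(sprintf("<raw_cube> subject %s, posture %s: %d x %d IF samples (%.1f s)\n",
              x$subject_id, x$posture, nrow(x$samples), ncol(x$samples),
              ncol(x$samples) / derived_params(x$config)$chirps_per_second))
  invisible(x)
}

#' Collapse the four acquisition postures to three recognition classes
#'
#' Left and right lateral are merged: supine -> 0, left/right lateral -> 1,
#' prone -> 2.
#'
#' @param posture Character vector of acquisition labels.
#' @return Integer vector of class indices in 0..2, with class names as a
#'   `labels` attribute.
#' @export
#' @examples
#' map_to_3class(c("supine", "right_lateral", "prone"))
map_to_3class <- function(posture) {
  idx <- match(posture, POSTURES4)
  if (anyNA(idx)) {
    stop("unknown posture label(s): ",
         paste(unique(posture[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  out <- c(0L, 1L, 1L, 2L)[idx]
  attr(out, "labels") <- POSTURES3[out + 1L]
  out
}

#' One-hot probability label for a posture
#'
#' @param posture A single acquisition posture label.
#' @return Numeric length-3 probability vector (one-hot), named by class.
#' @export
posture_onehot <- function(posture) {
  k <- map_to_3class(posture)
  y <- numeric(3L)
  y[k + 1L] <- 1
  names(y) <- POSTURES3
  y
}

#' Persist / restore a raw cube
#'
#' Cubes are stored with R-native serialisation; IF samples are truncated to
#' single precision on write (they are digitised quantities) and restored as
#' doubles.
#'
#' @param cube A `raw_cube`.
#' @param path File path.
#' @return `read_cube()` returns a `raw_cube`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "raw_cube"))
  saveRDS(cube, path)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  cube <- readRDS(path)
  stopifnot(inherits(cube, "raw_cube"))
  cube
}
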