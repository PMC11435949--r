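#' Motion-feature extraction parameters
#'
#' Geometry of the sliding-window standard-deviation features. Defaults match
#' a 640 chirps/s slow-time stream: window W = 320 samples (0.5 s), step
#' S = 64 samples (0.1 s), one feature image per 6 s span (N_W = 60 windows),
#' and a K1 = 40-bin range window.
#'
#' @param window_w Sliding-window width W in slow-time samples.
#' @param step_s Window step S in slow-time samples (S <= W).
#' @param span_s Slow-time span covered by one feature image (s).
#' @param k1 Number of contiguous range bins retained (bin-window height K1).
#' @return An object of class `feature_params`.
#' @export
feature_params <- function(window_w = 320L, step_s = 64L, span_s = 6,
                           k1 = 40L) {
  stopifnot(window_w > 0, step_s > 0, step_s <= window_w, span_s > 0, k1 > 0)
  structure(list(window_w = as.integer(window_w), step_s = as.integer(step_s),
                 span_s = as.numeric(span_s), k1 = as.integer(k1)),
            class = "feature_params")
}

#' Sliding-window standard deviation along slow time
#'
#' For every range bin, the population standard deviation (divide-by-W) of
#' each length-W window of the magnitude spectrogram, windows starting every
#' S samples. floor(N/S) windows are produced; the tail is edge-replicated by
#' W - S samples so the final windows are full length.
#'
#' @param mag Numeric K x N matrix (magnitude spectrogram), N >= W.
#' @param params A [feature_params()].
#' @return Numeric K x floor(N/S) matrix of standard deviations (>= 0).
#' @export
sliding_std <- function(mag, params) {
  stopifnot(is.matrix(mag))
  W <- params$window_w
  S <- params$step_s
  N <- ncol(mag)
  if (N < W) stop("slow-time length N < window width W", call. = FALSE)
  nw <- N %/% S
  pad <- W - S
  magp <- if (pad > 0) cbind(mag, mag[, rep.int(N, pad), drop = FALSE]) else mag
  cs1 <- cbind(0, t(apply(magp, 1L, cumsum)))
  cs2 <- cbind(0, t(apply(magp * magp, 1L, cumsum)))
  starts <- (seq_len(nw) - 1L) * S
  s1 <- cs1[, starts + W + 1L, drop = FALSE] - cs1[, starts + 1L, drop = FALSE]
  s2 <- cs2[, starts + W + 1L, drop = FALSE] - cs2[, starts + 1L, drop = FALSE]
  mu <- s1 / W
  sqrt(pmax(s2 / W - mu * mu, 0))
}

#' Optimal bin-window offset
#'
#' The 0-based offset of the K1-row window maximising the total standard
#' deviation (sum over the window's rows and all columns); ties broken by the
#' smallest offset.
#'
#' @param stdmat K x N_W matrix of sliding standard deviations.
#' @param k1 Window height in bins (<= K).
#' @return Integer 0-based row offset in `[0, K - k1]`.
#' @export
select_bin_window <- function(stdmat, k1) {
  stopifnot(is.matrix(stdmat))
  K <- nrow(stdmat)
  if (k1 > K) stop("bin window k1 exceeds number of range bins", call. = FALSE)
  cum <- c(0, cumsum(rowSums(stdmat)))
  win <- cum[(k1 + 1L):(K + 1L)] - cum[seq_len(K - k1 + 1L)]
  as.integer(which.max(win) - 1L)
}

#' Motion feature image
#'
#' A K1 x N_W matrix of sliding-window standard deviations cropped to the
#' optimal bin window, with its label as a probability vector over the three
#' posture classes (one-hot for raw data; soft after mix-up).
#'
#' @param values Non-negative K1 x N_W matrix.
#' @param bin_offset 0-based range-bin offset of the window start.
#' @param label Length-3 non-negative vector summing to 1.
#' @param subject_id Subject identifier.
#' @param posture Optional acquisition posture label.
#' @return An object of class `motion_feature_image`.
#' @export
motion_feature_image <- function(values, bin_offset, label, subject_id = "S0",
                                 posture = NA_character_) {
  stopifnot(is.matrix(values), all(values >= 0), length(label) == 3L,
            all(label >= -1e-9), abs(sum(label) - 1) < 1e-6)
  structure(list(values = values, bin_offset = as.integer(bin_offset),
                 label = as.numeric(label), subject_id = as.character(subject_id),
                 posture = posture),
            class = "motion_feature_image")
}

#' @export
print.motion_feature_image <- function(x, ...) {
  cat(sprintf("<motion_feature_image> %d x %d, offset %d, subject %s, label (%s)\n",
              nrow(x$values), ncol(x$values), x$bin_offset, x$subject_id,
              paste(signif(x$label, 3), collapse = ", ")))
  invisible(x)
}

#' Extract motion feature images from a spectrogram
#'
#' Slices the slow-time axis into consecutive spans of `span_s` seconds, and
#' per span computes the sliding standard deviations, selects the optimal bin
#' window (recomputed per image; the chosen offset is recorded on each
#' image), and crops to K1 x N_W.
#'
#' @param spectrogram A `range_spectrogram` with a known slow-time rate.
#' @param params A [feature_params()].
#' @param posture Acquisition posture providing the one-hot label, or NULL to
#'   pass `label` directly.
#' @param label Optional explicit probability label.
#' @param subject_id Subject identifier attached to each image.
#' @return List of [motion_feature_image()] objects, one per complete span.
#' @export
extract_feature_images <- function(spectrogram, params, posture = NULL,
                                   label = NULL, subject_id = "S0") {
  stopifnot(inherits(spectrogram, "range_spectrogram"))
  rate <- spectrogram$slow_time_rate_hz
  if (is.na(rate)) stop("spectrogram has no slow-time rate", call. = FALSE)
  if (!is.null(posture)) label <- posture_onehot(posture)
  if (is.null(label)) stop("either posture or label must be given", call. = FALSE)
  span_cols <- as.integer(round(params$span_s * rate))
  N <- ncol(spectrogram$magnitude)
  n_img <- N %/% span_cols
  if (n_img < 1L) stop("spectrogram shorter than one feature span", call. = FALSE)
  lapply(seq_len(n_img), function(i) {
    seg <- spectrogram$magnitude[, ((i - 1L) * span_cols + 1L):(i * span_cols),
                                 drop = FALSE]
    stdmat <- sliding_std(seg, params)
    off <- select_bin_window(stdmat, params$k1)
    motion_feature_image(stdmat[(off + 1L):(off + params$k1), , drop = FALSE],
                         bin_offset = off, label = label,
                         subject_id = subject_id,
                         posture = if (is.null(posture)) NA_character_ else posture)
  })
}

#' Raw range-FFT magnitude images (feature-ablation input)
#'
#' Companion to [extract_feature_images()] that skips the motion statistic
#' entirely: per span, the magnitude spectrogram is downsampled to the same
#' N_W columns by taking one chirp's magnitudes per feature step (snapshot
#' columns - averaging would itself be a temporal statistic), then cropped
#' to the K1-bin window with the most magnitude mass, producing images of
#' identical shape for the raw-input ablation.
#'
#' @inheritParams extract_feature_images
#' @return List of [motion_feature_image()] objects (same container; values
#'   are magnitudes, not standard deviations).
#' @export
extract_rawfft_images <- function(spectrogram, params, posture = NULL,
                                  label = NULL, subject_id = "S0") {
  stopifnot(inherits(spectrogram, "range_spectrogram"))
  rate <- spectrogram$slow_time_rate_hz
  if (is.na(rate)) stop("spectrogram has no slow-time rate", call. = FALSE)
  if (!is.null(posture)) label <- posture_onehot(posture)
  if (is.null(label)) stop("either posture or label must be given", call. = FALSE)
  span_cols <- as.integer(round(params$span_s * rate))
  N <- ncol(spectrogram$magnitude)
  n_img <- N %/% span_cols
  if (n_img < 1L) stop("spectrogram shorter than one feature span", call. = FALSE)
  S <- params$step_s
  nw <- span_cols %/% S
  K <- nrow(spectrogram$magnitude)
  lapply(seq_len(n_img), function(i) {
    seg <- spectrogram$magnitude[, ((i - 1L) * span_cols + 1L):(i * span_cols),
                                 drop = FALSE]
    ## one snapshot chirp per feature step (centre of each step)
    pooled <- seg[, seq.int(S %/% 2L, nw * S, by = S)[seq_len(nw)],
                  drop = FALSE]
    off <- select_bin_window(pooled, params$k1)
    motion_feature_image(pooled[(off + 1L):(off + params$k1), , drop = FALSE],
                         bin_offset = off, label = label,
                         subject_id = subject_id,
                         posture = if (is.null(posture)) NA_character_ else posture)
  })
}

#' @method autoplot motion_feature_image
#' @export
autoplot.motion_feature_image <- function(object, ...) {
  v <- object$values
  df <- expand.grid(bin = seq_len(nrow(v)) - 1L, window = seq_len(ncol(v)))
  df$std <- as.vector(v)
  ggplot2::ggplot(df, ggplot2::aes(.data$window, .data$bin, fill = .data$std)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "slow-time window", y = "range bin (within window)",
                  fill = "std") +
    ggplot2::theme_minimal()
}

#' Persist / restore a set of feature images
#'
#' @param images List of [motion_feature_image()] objects.
#' @param path File path.
#' @return `read_feature_set()` returns the list of images.
#' @export
write_feature_set <- function(images, path) {
  stopifnot(all(vapply(images, inherits, TRUE, "motion_feature_image")))
  saveRDS(images, path)
  invisible(path)
}

#' @rdname write_feature_set
#' @export
read_feature_set <- function(path) {
  readRDS(path)
}
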