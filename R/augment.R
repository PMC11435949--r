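#' Augmentation configuration
#'
#' Time shifts are drawn from [-1, -0.5] or [0.5, 1] seconds (mapped to whole
#' feature columns of 0.1 s), range shifts from [-10, -5] or [5, 10] bins,
#' and mix-up weights from Beta(alpha, alpha) with alpha < 1. Each technique
#' can be toggled for ablations.
#'
#' @param time_shift_range_s Magnitude interval of the time shift (s); the
#'   sign is drawn uniformly.
#' @param range_shift_bins Magnitude interval of the range shift (bins).
#' @param mixup_alpha Beta shape parameter, in (0, 1).
#' @param multiplicity Augmentation rounds per source image (0 disables).
#' @param column_pitch_s Slow-time duration of one feature column (s).
#' @param use_time_shift,use_range_shift,use_mixup Toggles for the three
#'   techniques.
#' @param seed Integer seed for all augmentation randomness.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(time_shift_range_s = c(0.5, 1),
                           range_shift_bins = c(5L, 10L),
                           mixup_alpha = 0.4,
                           multiplicity = 1L,
                           column_pitch_s = 0.1,
                           use_time_shift = TRUE,
                           use_range_shift = TRUE,
                           use_mixup = TRUE,
                           seed = 1L) {
  stopifnot(mixup_alpha > 0, mixup_alpha < 1, multiplicity >= 0,
            length(time_shift_range_s) == 2L, length(range_shift_bins) == 2L,
            time_shift_range_s[1] > 0, time_shift_range_s[1] <= time_shift_range_s[2],
            range_shift_bins[1] > 0, range_shift_bins[1] <= range_shift_bins[2])
  structure(list(time_shift_range_s = as.numeric(time_shift_range_s),
                 range_shift_bins = as.integer(range_shift_bins),
                 mixup_alpha = mixup_alpha,
                 multiplicity = as.integer(multiplicity),
                 column_pitch_s = column_pitch_s,
                 use_time_shift = isTRUE(use_time_shift),
                 use_range_shift = isTRUE(use_range_shift),
                 use_mixup = isTRUE(use_mixup),
                 seed = as.integer(seed)),
            class = "augment_config")
}

#' Circular time shift of a feature image
#'
#' Columns are rotated circularly (breathing is quasi-periodic, so wrapped
#' columns remain plausible and no columns are emptied). The offset must map
#' to a whole number of feature columns.
#'
#' @param img A [motion_feature_image()].
#' @param offset_s Shift in seconds; positive moves content to later columns.
#' @param column_pitch_s Duration of one feature column (s).
#' @return The shifted image (label and offset metadata unchanged).
#' @export
time_shift <- function(img, offset_s, column_pitch_s = 0.1) {
  stopifnot(inherits(img, "motion_feature_image"))
  k <- offset_s / column_pitch_s
  if (abs(k - round(k)) > 1e-6) {
    stop("time shift of ", offset_s, " s is not a whole number of ",
         column_pitch_s, " s columns", call. = FALSE)
  }
  k <- as.integer(round(k))
  nc <- ncol(img$values)
  k <- ((k %% nc) + nc) %% nc
  if (k > 0L) {
    img$values <- img$values[, c((nc - k + 1L):nc, seq_len(nc - k)), drop = FALSE]
  }
  img
}

#' Range shift of a feature image
#'
#' Rows are shifted along the range axis; vacated rows are zero-filled (body
#' energy must not wrap across the range axis).
#'
#' @param img A [motion_feature_image()].
#' @param offset_bins Integer shift; positive moves content toward higher
#'   bins. `|offset_bins|` must be < the image height.
#' @return The shifted image.
#' @export
range_shift <- function(img, offset_bins) {
  stopifnot(inherits(img, "motion_feature_image"))
  k <- as.integer(offset_bins)
  nr <- nrow(img$values)
  if (abs(k) >= nr) stop("range shift |", k, "| >= image height ", nr, call. = FALSE)
  if (k != 0L) {
    out <- matrix(0, nr, ncol(img$values))
    if (k > 0L) {
      out[(k + 1L):nr, ] <- img$values[seq_len(nr - k), , drop = FALSE]
    } else {
      out[seq_len(nr + k), ] <- img$values[(1L - k):nr, , drop = FALSE]
    }
    img$values <- out
  }
  img
}

#' Mix-up of two feature images
#'
#' Convex combination of two images and of their labels with weight `lam`:
#' the virtual sample lam*x_i + (1-lam)*x_j with label lam*y_i + (1-lam)*y_j.
#'
#' @param img_i,img_j Two [motion_feature_image()]s of identical shape.
#' @param lam Mixing weight in `[0, 1]`.
#' @return A [motion_feature_image()] with a (generally soft) label.
#' @export
mixup <- function(img_i, img_j, lam) {
  stopifnot(inherits(img_i, "motion_feature_image"),
            inherits(img_j, "motion_feature_image"),
            lam >= 0, lam <= 1)
  if (!identical(dim(img_i$values), dim(img_j$values))) {
    stop("mixup: image shape mismatch", call. = FALSE)
  }
  motion_feature_image(
    lam * img_i$values + (1 - lam) * img_j$values,
    bin_offset = img_i$bin_offset,
    label = lam * img_i$label + (1 - lam) * img_j$label,
    subject_id = img_i$subject_id
  )
}

## Draws one signed offset with magnitude uniform over `rng` (integer-valued
## for integer rng), sign +/- with equal probability.
sample_signed <- function(rng, integer = FALSE) {
  mag <- if (integer) sample(rng[1L]:rng[2L], 1L) else stats::runif(1L, rng[1L], rng[2L])
  sample(c(-1, 1), 1L) * mag
}

#' Augment a set of feature images
#'
#' Per augmentation round, each enabled technique contributes one new sample
#' per source image: a circular time shift, a zero-fill range shift, and a
#' mix-up with a randomly chosen partner of a *different* class (weight from
#' Beta(alpha, alpha)). Every augmented image records its provenance
#' (technique, parameters, source indices) in an `augmented` attribute.
#' Deterministic under the config seed.
#'
#' @param images List of [motion_feature_image()]s; at least two classes must
#'   be present when mix-up is enabled.
#' @param config An [augment_config()].
#' @return List of images: the originals followed by the augmented samples.
#' @export
augment_dataset <- function(images, config) {
  stopifnot(inherits(config, "augment_config"))
  if (config$multiplicity == 0L) return(images)
  hard <- vapply(images, function(im) which.max(im$label), 1L)
  if (config$use_mixup && length(unique(hard)) < 2L) {
    stop("mix-up requires images from at least two classes", call. = FALSE)
  }
  ## time-shift magnitudes must be representable as whole columns
  t_cols <- round(config$time_shift_range_s / config$column_pitch_s)
  withr::with_seed(config$seed, {
    out <- images
    for (r in seq_len(config$multiplicity)) {
      for (i in seq_along(images)) {
        if (config$use_time_shift) {
          k <- sample_signed(t_cols, integer = TRUE)
          im <- time_shift(images[[i]], k * config$column_pitch_s,
                           config$column_pitch_s)
          attr(im, "augmented") <- list(op = "time_shift", source = i,
                                        offset_cols = k)
          out[[length(out) + 1L]] <- im
        }
        if (config$use_range_shift) {
          k <- sample_signed(config$range_shift_bins, integer = TRUE)
          im <- range_shift(images[[i]], k)
          attr(im, "augmented") <- list(op = "range_shift", source = i,
                                        offset_bins = k)
          out[[length(out) + 1L]] <- im
        }
        if (config$use_mixup) {
          partners <- which(hard != hard[i])
          j <- partners[sample.int(length(partners), 1L)]
          lam <- stats::rbeta(1L, config$mixup_alpha, config$mixup_alpha)
          im <- mixup(images[[i]], images[[j]], lam)
          attr(im, "augmented") <- list(op = "mixup", source = c(i, j),
                                        lambda = lam)
          out[[length(out) + 1L]] <- im
        }
      }
    }
    out
  })
}
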