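#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations of the full pipeline (simulate ->
#' preprocess -> range-FFT -> features -> subject split -> augment training
#' split -> train -> evaluate). Stage seeds are all derived deterministically
#' from the single `seed`.
#'
#' The defaults define the synthetic benchmark: 9 subjects, 1 min per
#' posture, a 6/1/2 subject-wise train/validation/test split, the compact
#' ResTCN instantiation and 30 training epochs.
#'
#' @param n_subjects Number of simulated subjects.
#' @param minutes_per_posture Recording minutes per subject-posture.
#' @param split Integer vector `c(train, val, test)` of subject counts.
#' @param radar A [radar_config()].
#' @param feature A [feature_params()].
#' @param augment An [augment_config()] or NULL to disable augmentation.
#' @param model A [model_config()].
#' @param train A [train_config()].
#' @param checkpoint Checkpoint policy passed to [train_restcn()]; the
#'   benchmark default keeps the final epoch because its one-subject
#'   validation split ranks epochs unreliably.
#' @param input `"features"` for motion-feature images, `"raw_fft"` for
#'   block-averaged raw range-FFT magnitude images of the same shape.
#' @param variant Classifier variant: `"restcn"`, `"resnet_only"` or
#'   `"tcn_only"`.
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 9L,
                            minutes_per_posture = 1,
                            split = c(6L, 1L, 2L),
                            radar = radar_config(),
                            feature = feature_params(),
                            augment = augment_config(),
                            model = benchmark_model_config(),
                            train = train_config(epochs = 30L, batch_size = 64L),
                            checkpoint = "final",
                            input = c("features", "raw_fft"),
                            variant = c("restcn", "resnet_only", "tcn_only"),
                            seed = 1L) {
  stopifnot(length(split) == 3L, sum(split) == n_subjects)
  structure(list(n_subjects = as.integer(n_subjects),
                 minutes_per_posture = minutes_per_posture,
                 split = as.integer(split),
                 radar = radar, feature = feature, augment = augment,
                 model = model, train = train, checkpoint = checkpoint,
                 input = match.arg(input), variant = match.arg(variant),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

## deterministic per-stage seeds derived from the master seed
stage_seeds <- function(seed) {
  base <- (as.integer(seed) %% 1000000L) * 10L
  list(data = base + 1L, split = base + 2L, model = base + 3L,
       train = base + 4L, augment = base + 5L)
}

#' Simulate the benchmark dataset and extract both image types
#'
#' Generates one cube per subject-posture, runs preprocessing, the range FFT
#' and both feature extractors cube by cube (so only one raw cube is held in
#' memory at a time), and draws the subject-wise split.
#'
#' @param config A [pipeline_config()].
#' @return List with `features` and `rawfft` image lists, the `split`
#'   ([subject_split()]), and the scene `manifest` tibble.
#' @export
prepare_benchmark <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed)
  plan <- dataset_scenes(posture_presets(), config$n_subjects, config$radar,
                         seed = seeds$data)
  features <- list()
  rawfft <- list()
  for (i in seq_len(nrow(plan))) {
    cube <- synthesize_cube(plan$scene[[i]], config$radar,
                            duration_s = config$minutes_per_posture * 60,
                            subject_id = plan$subject_id[i],
                            posture = plan$posture[i])
    spec <- range_fft(preprocess_cube(cube))
    features <- c(features,
                  extract_feature_images(spec, config$feature,
                                         posture = plan$posture[i],
                                         subject_id = plan$subject_id[i]))
    rawfft <- c(rawfft,
                extract_rawfft_images(spec, config$feature,
                                      posture = plan$posture[i],
                                      subject_id = plan$subject_id[i]))
  }
  split <- subject_split(unique(plan$subject_id), config$split[1L],
                         config$split[2L], config$split[3L],
                         seed = seeds$split)
  list(features = features, rawfft = rawfft, split = split,
       manifest = plan[, c("subject_id", "posture", "class3")])
}

## subset an image list by the subjects of one split member
split_images <- function(images, ids) {
  images[vapply(images, function(im) im$subject_id %in% ids, TRUE)]
}

#' Train and evaluate one configuration on prepared benchmark data
#'
#' Selects the input representation, applies augmentation to the training
#' split only, builds the requested classifier variant and trains it with
#' validation-based checkpoint selection, then evaluates on the held-out
#' test subjects.
#'
#' @param prep Output of [prepare_benchmark()].
#' @param config A [pipeline_config()] (its `variant`, `input`, `augment`,
#'   `model` and `train` fields are used).
#' @return List with `report` ([eval_report()]), `fit` (`restcn_fit`) and
#'   `split`.
#' @export
fit_benchmark <- function(prep, config) {
  seeds <- stage_seeds(config$seed)
  images <- if (config$input == "features") prep$features else prep$rawfft
  tr <- split_images(images, prep$split$train)
  va <- split_images(images, prep$split$val)
  te <- split_images(images, prep$split$test)
  if (!is.null(config$augment)) {
    aug_cfg <- config$augment
    aug_cfg$seed <- seeds$augment
    tr <- augment_dataset(tr, aug_cfg)
  }
  mdl_cfg <- config$model
  mdl_cfg$seed <- seeds$model
  k1 <- nrow(tr[[1L]]$values)
  model <- if (config$variant == "restcn") build_restcn(mdl_cfg)
           else build_variant(config$variant, mdl_cfg, input_bins = k1)
  trn_cfg <- config$train
  trn_cfg$seed <- seeds$train
  fit <- train_restcn(model, tr, va, trn_cfg, checkpoint = config$checkpoint)
  list(report = evaluate_model(fit, te), fit = fit, split = prep$split)
}

#' Run the full synthetic pipeline
#'
#' simulate -> preprocess -> range-FFT -> features -> split -> augment
#' (training split only) -> train -> evaluate, all stages seeded from the
#' master seed. Identical configs give identical reports.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result`: list with `report`, `fit`, `split`,
#'   `manifest` and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  prep <- prepare_benchmark(config)
  res <- fit_benchmark(prep, config)
  structure(list(report = res$report, fit = res$fit, split = prep$split,
                 manifest = prep$manifest, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s on %s input\n",
              x$config$variant, x$config$input))
  print(x$report)
  invisible(x)
}

#' @rdname tidy.eval_report
#' @method glance pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) {
  cbind(tibble::tibble(variant = x$config$variant, input = x$config$input,
                       augmented = !is.null(x$config$augment),
                       seed = x$config$seed),
        glance(x$report))
}

#' Sweep one feature-geometry axis of the pipeline
#'
#' Re-runs the full pipeline once per value of the swept axis at a fixed
#' seed: `k1` (bin-window height, e.g. 30/40/50/60) or `span_s` (slow-time
#' span per image, e.g. 2/6/10 s). The model input shape is rebuilt per
#' sweep point.
#'
#' @param config Base [pipeline_config()].
#' @param axis `"k1"` or `"span_s"`.
#' @param values Numeric vector of axis values.
#' @return A tibble: one row per value with the evaluation summary.
#' @export
run_sweep <- function(config, axis = c("k1", "span_s"), values) {
  axis <- match.arg(axis)
  stopifnot(length(values) >= 1)
  rows <- lapply(values, function(v) {
    cfg <- config
    if (axis == "k1") cfg$feature$k1 <- as.integer(v)
    else cfg$feature$span_s <- as.numeric(v)
    res <- run_pipeline(cfg)
    cbind(tibble::tibble(axis = axis, value = v), glance(res$report))
  })
  do.call(rbind, rows)
}

#' Write a subject-posture manifest CSV
#'
#' @param manifest Tibble with at least subject_id and posture columns.
#' @param path File path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE)
  invisible(path)
}
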