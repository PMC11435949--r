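#' ResTCN architecture configuration
#'
#' Hyperparameters of the two-stage classifier: a residual convolutional
#' backbone that collapses the range axis of a feature image while preserving
#' a (pooled) temporal axis, a per-time-step linear projection to an
#' embedding, and a causal dilated temporal-convolution stack whose last time
#' step feeds the classification layer.
#'
#' The defaults instantiate the full-size network: four residual stages with
#' 64/128/256/512 channels, a 1024-dimensional embedding per time step, and
#' three weight-heavy TCN blocks of 256 channels with dilations 1, 2, 4. For
#' CPU-bound benchmarking see [benchmark_model_config()], a compact
#' instantiation of the same architecture.
#'
#' @param n_classes Number of output classes.
#' @param stage_channels Channel counts of the residual stages; each stage
#'   strides 2 on the range axis only.
#' @param embedding_dim Per-time-step embedding length after the backbone.
#' @param tcn_channels Channel counts of the TCN residual blocks.
#' @param tcn_kernel Temporal kernel size.
#' @param tcn_dilations Dilation per TCN block; strictly increasing powers
#'   of 2.
#' @param dropout Dropout probability inside TCN blocks.
#' @param temporal_pool Integer factor of the initial temporal average pool
#'   (60 columns / 4 = 15 time steps by default).
#' @param seed Seed for weight initialisation.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_classes = 3L,
                         stage_channels = c(64L, 128L, 256L, 512L),
                         embedding_dim = 1024L,
                         tcn_channels = c(256L, 256L, 256L),
                         tcn_kernel = 3L,
                         tcn_dilations = c(1L, 2L, 4L),
                         dropout = 0.1,
                         temporal_pool = 4L,
                         seed = 1L) {
  stopifnot(n_classes >= 2, length(stage_channels) >= 1,
            all(stage_channels > 0), embedding_dim > 0,
            length(tcn_channels) == length(tcn_dilations),
            tcn_kernel >= 1, dropout >= 0, dropout < 1, temporal_pool >= 1)
  dil <- as.integer(tcn_dilations)
  pow2 <- 2^(seq_along(dil) - 1L)
  if (!all(dil == pow2)) {
    stop("tcn_dilations must be strictly increasing powers of 2 (1, 2, 4, ...)",
         call. = FALSE)
  }
  structure(list(n_classes = as.integer(n_classes),
                 stage_channels = as.integer(stage_channels),
                 embedding_dim = as.integer(embedding_dim),
                 tcn_channels = as.integer(tcn_channels),
                 tcn_kernel = as.integer(tcn_kernel),
                 tcn_dilations = dil,
                 dropout = dropout,
                 temporal_pool = as.integer(temporal_pool),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Compact ResTCN configuration for CPU benchmarking
#'
#' Same architecture as [model_config()] at a size a single CPU core trains
#' in about a minute on the synthetic benchmark: stages 8/8/16/16, 32-d
#' embedding, three 16-channel TCN blocks.
#'
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
benchmark_model_config <- function(...) {
  args <- list(stage_channels = c(8L, 8L, 16L, 16L),
               embedding_dim = 32L,
               tcn_channels = c(16L, 16L, 16L))
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

## assemble the TCN stack as a layer list
tcn_stack <- function(c_in, config) {
  layers <- list()
  for (i in seq_along(config$tcn_channels)) {
    layers[[i]] <- layer_tcn_block(c_in, config$tcn_channels[i],
                                   kernel = config$tcn_kernel,
                                   dilation = config$tcn_dilations[i],
                                   dropout = config$dropout)
    c_in <- config$tcn_channels[i]
  }
  layers
}

## backbone shared by restcn and resnet_only: clone to 3 channels, strided
## stem, temporal pool, residual stages, range collapse, projection to the
## per-step embedding
backbone_layers <- function(config) {
  ch <- config$stage_channels
  ## the temporal pool precedes the stem so every convolution runs at the
  ## pooled step count (15 steps for the default 60-column image)
  layers <- list(
    layer_clone3(),
    layer_tpool(config$temporal_pool),
    layer_conv2d(3L, ch[1L], stride = c(2L, 1L)),
    layer_batchnorm(ch[1L]),
    layer_relu()
  )
  c_prev <- ch[1L]
  for (c_i in ch) {
    layers[[length(layers) + 1L]] <- layer_res2d(c_prev, c_i, stride_h = 2L)
    c_prev <- c_i
  }
  layers[[length(layers) + 1L]] <- layer_range_mean()
  layers[[length(layers) + 1L]] <- layer_conv1d(c_prev, config$embedding_dim,
                                                kernel = 1L)
  layers[[length(layers) + 1L]] <- layer_relu()
  layers
}

new_model <- function(kind, config, layers) {
  structure(list(kind = kind, config = config, layers = layers),
            class = "restcn_model")
}

#' Build the ResTCN classifier
#'
#' Replicates the 1-channel feature image to 3 channels, extracts a sequence
#' of per-time-step embeddings with the residual backbone, runs the causal
#' dilated TCN over that sequence, and classifies from the last time step.
#' Weight initialisation is deterministic in `config$seed`.
#'
#' @param config A [model_config()].
#' @return A `restcn_model`.
#' @export
build_restcn <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  withr::with_seed(config$seed, {
    layers <- backbone_layers(config)
    layers <- c(layers, tcn_stack(config$embedding_dim, config))
    layers[[length(layers) + 1L]] <- layer_last_step()
    layers[[length(layers) + 1L]] <- layer_linear(
      config$tcn_channels[length(config$tcn_channels)], config$n_classes)
    new_model("restcn", config, layers)
  })
}

#' Build an ablation variant of the classifier
#'
#' `resnet_only`: the residual backbone followed by global temporal average
#' pooling and a fully connected layer (no TCN). `tcn_only`: the feature
#' image is read directly as a length-N_W sequence of K1-dimensional vectors
#' into the TCN, classifying from the last time step (no backbone).
#'
#' @param name One of `"resnet_only"`, `"tcn_only"`.
#' @param config A [model_config()].
#' @param input_bins For `tcn_only`, the image height K1 (the sequence's
#'   channel width).
#' @return A `restcn_model`.
#' @export
build_variant <- function(name = c("resnet_only", "tcn_only"),
                          config = model_config(), input_bins = 40L) {
  name <- match.arg(name)
  stopifnot(inherits(config, "model_config"))
  withr::with_seed(config$seed, {
    if (name == "resnet_only") {
      layers <- backbone_layers(config)
      layers[[length(layers) + 1L]] <- layer_time_mean()
      layers[[length(layers) + 1L]] <- layer_linear(config$embedding_dim,
                                                    config$n_classes)
    } else {
      layers <- tcn_stack(as.integer(input_bins), config)
      layers[[length(layers) + 1L]] <- layer_last_step()
      layers[[length(layers) + 1L]] <- layer_linear(
        config$tcn_channels[length(config$tcn_channels)], config$n_classes)
    }
    new_model(name, config, layers)
  })
}

## forward pass to logits. x: (K1, NW, B) array. The tcn_only variant reads
## the image directly as a (C = K1, T = NW, B) sequence; the image models
## get the channel-cloning layer as their first layer.
model_logits <- function(model, x, train = FALSE) {
  stopifnot(length(dim(x)) == 3L)
  for (l in model$layers) x <- l$forward(x, train)
  x
}

model_backward <- function(model, dlogits) {
  d <- dlogits
  for (l in rev(model$layers)) d <- l$backward(d)
  invisible(d)
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2L, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

#' Class probabilities for a batch of feature images
#'
#' @param object A `restcn_model`.
#' @param images List of [motion_feature_image()]s or a (K1, NW, B) array.
#' @param ... Unused.
#' @return A B x n_classes matrix of probabilities (rows sum to 1), columns
#'   named by posture class.
#' @export
predict.restcn_model <- function(object, images, ...) {
  x <- if (is.array(images) && length(dim(images)) == 3L) images
       else stack_images(images)$x
  p <- t(softmax_cols(model_logits(object, x, train = FALSE)))
  colnames(p) <- POSTURES3[seq_len(object$config$n_classes)]
  p
}

#' Number of trainable parameters of a model
#'
#' @param model A `restcn_model`.
#' @return Integer parameter count.
#' @export
n_params <- function(model) {
  sum(vapply(collect_layers(model$layers),
             function(l) sum(vapply(l$params, length, 1L)), 1L))
}

#' @export
print.restcn_model <- function(x, ...) {
  prim <- collect_layers(x$layers)
  cat(sprintf("<restcn_model> variant %s: %d primitive layers, %d parameters\n",
              x$kind, length(prim), n_params(x)))
  for (l in prim) {
    np <- sum(vapply(l$params, length, 1L))
    cat(sprintf("  %-10s %s\n", l$type,
                if (np > 0) paste0(np, " params") else ""))
  }
  invisible(x)
}
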