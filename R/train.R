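#' Training recipe configuration
#'
#' The published recipe: AdamW on the categorical cross entropy, initial
#' learning rate 0.005 with decoupled weight decay 0.001, learning rate
#' scaled down 10-fold every 10 epochs, 100 epochs. Batch size is not part
#' of the printed recipe; 32 is the default.
#'
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param initial_lr Initial learning rate.
#' @param weight_decay Decoupled (L2-style) weight-decay coefficient.
#' @param lr_decay_factor Multiplicative factor of each learning-rate step.
#' @param lr_decay_every_epochs Epoch interval between steps.
#' @param seed Seed for shuffling and dropout.
#' @param verbose Print a line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 100L, batch_size = 32L, initial_lr = 0.005,
                         weight_decay = 0.001, lr_decay_factor = 0.1,
                         lr_decay_every_epochs = 10L, seed = 1L,
                         verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, initial_lr > 0,
            lr_decay_factor > 0, lr_decay_every_epochs >= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 initial_lr = initial_lr, weight_decay = weight_decay,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every_epochs = as.integer(lr_decay_every_epochs),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Learning rate at a given epoch under the step schedule
#'
#' @param config A [train_config()].
#' @param epoch 0-based epoch index.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$initial_lr *
    config$lr_decay_factor^(epoch %/% config$lr_decay_every_epochs)
}

#' Subject-wise random split
#'
#' Partitions subjects (not samples) into train/validation/test so no
#' individual contributes to more than one split.
#'
#' @param subject_ids Character vector (duplicates allowed; the distinct set
#'   is partitioned).
#' @param n_train,n_val,n_test Split sizes; must sum to the number of
#'   distinct subjects.
#' @param seed Integer seed.
#' @return A `split_spec`: list with `train`, `val`, `test` id vectors.
#' @export
subject_split <- function(subject_ids, n_train, n_val, n_test, seed = 1L) {
  ids <- sort(unique(as.character(subject_ids)))
  if (n_train + n_val + n_test != length(ids)) {
    stop("n_train + n_val + n_test = ", n_train + n_val + n_test,
         " but there are ", length(ids), " distinct subjects", call. = FALSE)
  }
  perm <- withr::with_seed(as.integer(seed), sample(ids))
  structure(list(train = sort(perm[seq_len(n_train)]),
                 val = sort(perm[n_train + seq_len(n_val)]),
                 test = sort(perm[n_train + n_val + seq_len(n_test)])),
            class = "split_spec")
}

#' Stack feature images into training tensors
#'
#' @param images List of [motion_feature_image()]s of identical shape.
#' @return List with `x` (K1 x N_W x B array), `y` (3 x B label matrix),
#'   `subjects` (character), `hard` (integer 0-based argmax classes).
#' @export
stack_images <- function(images) {
  stopifnot(length(images) > 0)
  d <- dim(images[[1L]]$values)
  x <- array(0, c(d, length(images)))
  y <- matrix(0, length(images[[1L]]$label), length(images))
  for (i in seq_along(images)) {
    x[, , i] <- images[[i]]$values
    y[, i] <- images[[i]]$label
  }
  list(x = x, y = y,
       subjects = vapply(images, function(im) im$subject_id, ""),
       hard = vapply(images, function(im) which.max(im$label) - 1L, 1L))
}

#' Batch-mean categorical cross entropy
#'
#' Mean over the batch of -sum_c y_c log(p_c); supports soft labels (e.g.
#' from mix-up).
#'
#' @param probabilities n_classes x B matrix of predicted probabilities.
#' @param labels n_classes x B matrix of (possibly soft) labels on the
#'   simplex.
#' @return Non-negative scalar loss.
#' @export
cross_entropy_loss <- function(probabilities, labels) {
  stopifnot(identical(dim(probabilities), dim(labels)))
  if (any(!is.finite(probabilities))) {
    stop("non-finite probabilities", call. = FALSE)
  }
  -mean(colSums(labels * log(pmax(probabilities, 1e-12))))
}

#' Train a classifier on feature images
#'
#' Mini-batch AdamW with the step learning-rate schedule; records per-epoch
#' training and validation loss/accuracy and restores the parameters of the
#' epoch with the best validation accuracy (last epoch when no validation
#' set is given). Fully reproducible from the config seed.
#'
#' @param model A `restcn_model` from [build_restcn()] or [build_variant()].
#' @param train_images Non-empty list of [motion_feature_image()]s.
#' @param val_images Optional validation list.
#' @param config A [train_config()].
#' @param checkpoint `"best_val"` restores the parameters of the epoch with
#'   the highest validation accuracy; `"final"` keeps the last epoch (the
#'   validation curve is still recorded). With very small validation sets
#'   (one subject) epoch ranking by validation accuracy is noisy and
#'   `"final"` is the more reliable choice.
#' @return A `restcn_fit`: list with the trained `model`, `history` tibble
#'   (epoch, lr, train_loss, train_acc, val_loss, val_acc) and `best_epoch`.
#' @export
train_restcn <- function(model, train_images, val_images = NULL,
                         config = train_config(),
                         checkpoint = c("best_val", "final")) {
  checkpoint <- match.arg(checkpoint)
  stopifnot(inherits(model, "restcn_model"), inherits(config, "train_config"))
  if (length(train_images) == 0) stop("empty training set", call. = FALSE)
  tr <- stack_images(train_images)
  va <- if (length(val_images)) stack_images(val_images) else NULL
  prim <- collect_layers(model$layers)
  opt <- adamw_new(prim, lr = config$initial_lr,
                   weight_decay = config$weight_decay)
  n <- dim(tr$x)[3L]
  hist <- vector("list", config$epochs)
  best_acc <- -Inf
  best_epoch <- NA_integer_
  best_snap <- NULL
  withr::with_seed(config$seed, {
    for (epoch in 0:(config$epochs - 1L)) {
      lr <- lr_at_epoch(config, epoch)
      idx <- sample.int(n)
      loss_sum <- 0; acc_sum <- 0
      starts <- seq(1L, n, by = config$batch_size)
      for (s in starts) {
        b <- idx[s:min(s + config$batch_size - 1L, n)]
        xb <- tr$x[, , b, drop = FALSE]
        yb <- tr$y[, b, drop = FALSE]
        logits <- model_logits(model, xb, train = TRUE)
        p <- softmax_cols(logits)
        loss_sum <- loss_sum + cross_entropy_loss(p, yb) * length(b)
        acc_sum <- acc_sum +
          sum(max.col(t(logits)) == apply(yb, 2L, which.max))
        model_backward(model, (p - yb) / length(b))
        adamw_step(opt, lr)
      }
      ev <- if (is.null(va)) c(NA_real_, NA_real_) else {
        pv <- eval_probs(model, va$x)
        c(cross_entropy_loss(pv, va$y),
          mean(max.col(t(pv)) == apply(va$y, 2L, which.max)))
      }
      hist[[epoch + 1L]] <- tibble::tibble(
        epoch = epoch, lr = lr,
        train_loss = loss_sum / n, train_acc = acc_sum / n,
        val_loss = ev[1L], val_acc = ev[2L])
      track <- if (is.null(va) || checkpoint == "final") acc_sum / n else ev[2L]
      if (!is.na(track) && track > best_acc) {
        best_acc <- track
        best_epoch <- epoch
        best_snap <- snapshot_params(prim)
      }
      if (config$verbose) {
        cat(sprintf("epoch %3d lr %.5f loss %.4f acc %.3f val %.3f\n",
                    epoch, lr, loss_sum / n, acc_sum / n, ev[2L]))
      }
    }
  })
  if (checkpoint == "best_val" && !is.null(va) && !is.null(best_snap)) {
    restore_params(prim, best_snap)
  } else {
    best_epoch <- config$epochs - 1L
  }
  structure(list(model = model, history = do.call(rbind, hist),
                 best_epoch = best_epoch, config = config),
            class = "restcn_fit")
}

## forward in eval mode, batched to bound memory
eval_probs <- function(model, x, batch_size = 64L) {
  n <- dim(x)[3L]
  out <- matrix(0, model$config$n_classes, n)
  for (s in seq(1L, n, by = batch_size)) {
    b <- s:min(s + batch_size - 1L, n)
    out[, b] <- softmax_cols(model_logits(model, x[, , b, drop = FALSE],
                                          train = FALSE))
  }
  out
}

#' @export
print.restcn_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<restcn_fit> %s: %d epochs, best epoch %d\n",
              x$model$kind, nrow(h), x$best_epoch))
  cat(sprintf("  final train acc %.3f, best val acc %.3f\n",
              h$train_acc[nrow(h)],
              if (all(is.na(h$val_acc))) NA else max(h$val_acc, na.rm = TRUE)))
  invisible(x)
}

#' Broom-style accessors for a fitted classifier
#'
#' `tidy()` returns the per-epoch training history; `glance()` a one-row
#' summary.
#'
#' @param x A `restcn_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy restcn_fit
#' @export
tidy.restcn_fit <- function(x, ...) x$history

#' @rdname tidy.restcn_fit
#' @method glance restcn_fit
#' @export
glance.restcn_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    variant = x$model$kind,
    epochs = nrow(h),
    n_parameters = n_params(x$model),
    best_epoch = x$best_epoch,
    final_train_acc = h$train_acc[nrow(h)],
    best_val_acc = if (all(is.na(h$val_acc))) NA_real_
                   else max(h$val_acc, na.rm = TRUE)
  )
}

#' @method autoplot restcn_fit
#' @export
autoplot.restcn_fit <- function(object, ...) {
  h <- object$history
  df <- rbind(
    data.frame(epoch = h$epoch, metric = "loss", split = "train", value = h$train_loss),
    data.frame(epoch = h$epoch, metric = "loss", split = "val", value = h$val_loss),
    data.frame(epoch = h$epoch, metric = "accuracy", split = "train", value = h$train_acc),
    data.frame(epoch = h$epoch, metric = "accuracy", split = "val", value = h$val_acc)
  )
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(.data$epoch, .data$value, colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
}
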