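test_that("model configuration enforces the dilation ladder", {
  expect_s3_class(model_config(), "model_config")
  expect_identical(model_config()$embedding_dim, 1024L)
  expect_error(model_config(tcn_dilations = c(1L, 3L), tcn_channels = c(8L, 8L)),
               "powers of 2")
})

test_that("the default architecture emits 3 logits from a 1024-d embedding", {
  mdl <- build_restcn(model_config(seed = 1L))
  proj <- Filter(function(l) l$type == "conv1d",
                 collect_layers(mdl$layers))[[1L]]
  expect_identical(nrow(proj$params$W), 1024L)  # per-step embedding length
  x <- array(abs(stats::rnorm(40 * 60 * 2)), c(40, 60, 2))
  p <- predict(mdl, x)
  expect_identical(dim(p), c(2L, 3L))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
})

test_that("builds and forward passes are deterministic; batches independent", {
  cfg <- tiny_model_cfg(seed = 5L)
  m1 <- build_restcn(cfg)
  m2 <- build_restcn(cfg)
  l1 <- collect_layers(m1$layers)
  l2 <- collect_layers(m2$layers)
  for (i in seq_along(l1)) expect_identical(l1[[i]]$params, l2[[i]]$params)
  x <- array(abs(withr::with_seed(2, stats::rnorm(12 * 8 * 4))), c(12, 8, 4))
  p1 <- predict(m1, x)
  p2 <- predict(m1, x)
  expect_identical(p1, p2)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(predict(m1, x[, , perm]), p1[perm, ], tolerance = 1e-12)
})

test_that("ablation variants have the published shapes and sizes", {
  cfg <- tiny_model_cfg()
  full <- build_restcn(cfg)
  resnet <- build_variant("resnet_only", cfg)
  tcn <- build_variant("tcn_only", cfg, input_bins = 40L)
  x <- array(abs(stats::rnorm(40 * 60 * 2)), c(40, 60, 2))
  expect_identical(dim(predict(resnet, x)), c(2L, 3L))
  expect_identical(dim(predict(tcn, x)), c(2L, 3L))    # 40-dim x 60-step sequence
  expect_lt(n_params(resnet), n_params(full))           # no TCN stack
  expect_error(build_variant("lstm_only", cfg))
})

test_that("the TCN stack is causal", {
  cfg <- tiny_model_cfg(seed = 3L, dropout = 0)
  stack <- withr::with_seed(1, radarposture:::tcn_stack(5L, cfg))
  x <- array(stats::rnorm(5 * 20 * 1), c(5, 20, 1))
  x2 <- x
  k <- 4L
  x2[, (20L - k + 1L):20L, ] <- 0               # perturb only the last k steps
  fwd <- function(z) {
    for (l in stack) z <- l$forward(z, train = FALSE)
    z
  }
  y1 <- fwd(x)
  y2 <- fwd(x2)
  expect_equal(y1[, 1:(20L - k), , drop = FALSE],
               y2[, 1:(20L - k), , drop = FALSE], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(y1[, 20L, ], y2[, 20L, ])))
})

test_that("analytic gradients match finite differences", {
  mdl <- build_restcn(tiny_model_cfg(seed = 7L, dropout = 0))
  x <- array(abs(withr::with_seed(42, stats::rnorm(12 * 8 * 3))), c(12, 8, 3))
  y <- diag(3)
  prim <- collect_layers(mdl$layers)
  loss_fn <- function() {
    snap <- radarposture:::snapshot_params(prim)
    p <- radarposture:::softmax_cols(model_logits(mdl, x, train = TRUE))
    radarposture:::restore_params(prim, snap)
    cross_entropy_loss(p, y)
  }
  p <- radarposture:::softmax_cols(model_logits(mdl, x, train = TRUE))
  model_backward(mdl, (p - y) / 3)
  worst <- 0
  withr::with_seed(1, {
    for (l in prim) {
      for (nm in names(l$params)) {
        for (ii in sample(length(l$params[[nm]]),
                          min(2L, length(l$params[[nm]])))) {
          eps <- 1e-5
          orig <- l$params[[nm]][ii]
          l$params[[nm]][ii] <- orig + eps
          lp <- loss_fn()
          l$params[[nm]][ii] <- orig - eps
          lm <- loss_fn()
          l$params[[nm]][ii] <- orig
          num <- (lp - lm) / (2 * eps)
          ana <- l$grads[[nm]][ii]
          worst <- max(worst, abs(num - ana) / max(1e-7, abs(num) + abs(ana)))
        }
      }
    }
  })
  expect_lt(worst, 1e-3)
})

test_that("every trainable tensor receives gradient", {
  mdl <- build_restcn(tiny_model_cfg(seed = 9L, dropout = 0))
  x <- array(abs(withr::with_seed(3, stats::rnorm(12 * 8 * 6))), c(12, 8, 6))
  y <- matrix(0, 3, 6)
  y[cbind(rep(1:3, 2), 1:6)] <- 1
  p <- radarposture:::softmax_cols(model_logits(mdl, x, train = TRUE))
  model_backward(mdl, (p - y) / 6)
  for (l in collect_layers(mdl$layers)) {
    for (nm in names(l$params)) {
      expect_gt(max(abs(l$grads[[nm]])), 0)
    }
  }
})

test_that("the network can overfit a small labelled set", {
  imgs <- toy_labelled_images(n_per_class = 3L)
  mdl <- build_restcn(model_config(stage_channels = c(4L, 8L),
                                   embedding_dim = 16L,
                                   tcn_channels = c(8L, 8L),
                                   tcn_dilations = c(1L, 2L),
                                   dropout = 0, temporal_pool = 2L, seed = 2L))
  cfg <- train_config(epochs = 25L, batch_size = 9L, seed = 4L,
                      lr_decay_every_epochs = 10L)
  fit <- train_restcn(mdl, imgs, config = cfg)       # 25 steps of batch 9
  expect_equal(fit$history$train_acc[nrow(fit$history)], 1)
  expect_lt(fit$history$train_loss[nrow(fit$history)],
            fit$history$train_loss[1L])
})
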