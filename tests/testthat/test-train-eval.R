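test_that("the step learning-rate schedule decays tenfold every ten epochs", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 0), 0.005)
  expect_equal(lr_at_epoch(cfg, 9), 0.005)
  expect_equal(lr_at_epoch(cfg, 10), 0.0005)
  expect_equal(lr_at_epoch(cfg, 20), 0.00005)
})

test_that("subject-wise splits partition subjects exactly", {
  ids <- sprintf("P%02d", 1:16)
  sp <- subject_split(ids, 8L, 2L, 6L, seed = 3L)
  expect_length(sp$train, 8L)
  expect_length(sp$val, 2L)
  expect_length(sp$test, 6L)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_identical(sp, subject_split(ids, 8L, 2L, 6L, seed = 3L))
  expect_false(identical(sp, subject_split(ids, 8L, 2L, 6L, seed = 4L)))
  expect_error(subject_split(ids, 8L, 2L, 5L), "15")
})

test_that("every image of a subject lands in exactly one split", {
  imgs <- unlist(lapply(sprintf("Q%d", 1:5), function(sid) {
    lapply(1:3, function(i) toy_image(6L, 8L, "supine", i, subject = sid))
  }), recursive = FALSE)
  sp <- subject_split(vapply(imgs, function(x) x$subject_id, ""), 3L, 1L, 1L,
                      seed = 1L)
  member <- vapply(imgs, function(im) {
    sum(im$subject_id %in% sp$train, im$subject_id %in% sp$val,
        im$subject_id %in% sp$test)
  }, 0L)
  expect_true(all(member == 1L))
})

test_that("cross entropy matches its closed forms", {
  one_hot <- matrix(c(1, 0, 0), 3, 1)
  expect_equal(cross_entropy_loss(one_hot, one_hot), 0, tolerance = 1e-10)
  expect_equal(cross_entropy_loss(matrix(1 / 3, 3, 1), one_hot), log(3))
  soft <- matrix(c(0.5, 0, 0.5), 3, 1)
  expect_equal(cross_entropy_loss(soft, soft), log(2))
  expect_error(cross_entropy_loss(matrix(NaN, 3, 1), one_hot), "non-finite")
})

test_that("evaluation metrics follow the one-vs-rest definitions", {
  perfect <- eval_report(truth = rep(0:2, each = 5), predicted = rep(0:2, each = 5))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_precision, 1)
  expect_equal(perfect$macro_recall, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(unname(diag(perfect$confusion)), rep(5L, 3))

  ## binary-style counts: TP=8 FP=2 FN=2 TN=18 for the first class
  truth <- c(rep(0L, 10), rep(1L, 20))
  pred <- c(rep(0L, 8), rep(1L, 2), rep(0L, 2), rep(1L, 18))
  r <- eval_report(truth, pred, n_classes = 2L)
  expect_equal(r$per_class$tp[1L], 8L)
  expect_equal(r$per_class$fp[1L], 2L)
  expect_equal(r$per_class$fn[1L], 2L)
  expect_equal(r$per_class$tn[1L], 18L)
  expect_equal(r$per_class$precision[1L], 0.8)
  expect_equal(r$per_class$recall[1L], 0.8)
  expect_equal(r$per_class$f1[1L], 0.8)
})

test_that("accuracy equals the confusion trace over a brute-force recount", {
  set.seed(21)
  truth <- sample(0:2, 200, replace = TRUE)
  pred <- sample(0:2, 200, replace = TRUE)
  r <- eval_report(truth, pred)
  expect_equal(r$accuracy, mean(truth == pred))
  expect_equal(sum(r$confusion), 200L)
  expect_gte(r$macro_f1, 0)
  expect_lte(r$macro_f1, 1)
})

test_that("a class missing from the test set is flagged", {
  expect_warning(r <- eval_report(c(0L, 0L, 1L), c(0L, 1L, 1L)), "absent")
  expect_identical(r$missing_classes, "prone")
  expect_equal(r$per_class$precision[3L], 0)
  expect_equal(r$per_class$recall[3L], 0)
})

test_that("training records history, schedules the rate and is reproducible", {
  imgs <- toy_labelled_images(n_per_class = 2L)
  cfg <- train_config(epochs = 12L, batch_size = 6L, seed = 5L)
  mk <- function() build_restcn(tiny_model_cfg(seed = 6L))
  f1 <- train_restcn(mk(), imgs, imgs, cfg)
  f2 <- train_restcn(mk(), imgs, imgs, cfg)
  expect_identical(nrow(f1$history), 12L)
  expect_equal(f1$history$lr[1L], 0.005)
  expect_equal(f1$history$lr[11L], 0.0005)
  expect_identical(f1$history, f2$history)
  expect_error(train_restcn(mk(), list(), config = cfg), "empty")
  g <- glance(f1)
  expect_identical(g$epochs, 12L)
  expect_s3_class(tidy(f1), "tbl_df")
})

test_that("checkpoint policies restore different parameter sets", {
  imgs <- toy_labelled_images(n_per_class = 2L)
  cfg <- train_config(epochs = 6L, batch_size = 6L, seed = 5L)
  f_best <- train_restcn(build_restcn(tiny_model_cfg(seed = 6L)), imgs, imgs,
                         cfg, checkpoint = "best_val")
  f_final <- train_restcn(build_restcn(tiny_model_cfg(seed = 6L)), imgs, imgs,
                          cfg, checkpoint = "final")
  expect_identical(f_final$best_epoch, 5L)
  expect_lte(f_best$best_epoch, 5L)
})
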