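#' Evaluate a classifier on a labelled test set
#'
#' Builds the 3x3 confusion matrix (rows = true, columns = predicted) and
#' computes, per class one-vs-rest, TP/FP/FN/TN and precision, recall and F1
#' (2 P R / (P + R)); macro averages are the unweighted class means and
#' accuracy is the confusion trace over the sample count. A class absent
#' from the test set gets zero metrics and raises a warning flag.
#'
#' @param model A `restcn_model` or `restcn_fit`.
#' @param test_images Non-empty list of labelled [motion_feature_image()]s
#'   (hard labels).
#' @return An `eval_report`: list with `confusion`, `per_class` tibble,
#'   `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`, `n`,
#'   `missing_classes`.
#' @export
evaluate_model <- function(model, test_images) {
  if (inherits(model, "restcn_fit")) model <- model$model
  stopifnot(inherits(model, "restcn_model"))
  if (length(test_images) == 0) stop("empty test set", call. = FALSE)
  st <- stack_images(test_images)
  probs <- eval_probs(model, st$x)
  pred <- max.col(t(probs)) - 1L
  eval_report(truth = st$hard, predicted = pred,
              n_classes = model$config$n_classes)
}

#' Classification report from truth/prediction vectors
#'
#' @param truth,predicted Integer vectors of 0-based class indices.
#' @param n_classes Number of classes.
#' @return An `eval_report`.
#' @export
eval_report <- function(truth, predicted, n_classes = 3L) {
  stopifnot(length(truth) == length(predicted))
  lev <- 0:(n_classes - 1L)
  conf <- table(factor(truth, levels = lev), factor(predicted, levels = lev))
  conf <- matrix(as.integer(conf), n_classes, n_classes,
                 dimnames = list(true = POSTURES3[seq_len(n_classes)],
                                 predicted = POSTURES3[seq_len(n_classes)]))
  n <- sum(conf)
  per <- lapply(seq_len(n_classes), function(k) {
    tp <- conf[k, k]
    fp <- sum(conf[-k, k])
    fn <- sum(conf[k, -k])
    tn <- n - tp - fp - fn
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    tibble::tibble(class = POSTURES3[k], tp = tp, fp = fp, fn = fn, tn = tn,
                   precision = prec, recall = rec, f1 = f1,
                   support = tp + fn)
  })
  per <- do.call(rbind, per)
  missing <- per$class[per$support == 0]
  if (length(missing)) {
    warning("class(es) absent from test set: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(confusion = conf,
                 per_class = per,
                 accuracy = sum(diag(conf)) / n,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 n = n,
                 missing_classes = missing),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d, accuracy %.4f, macro P/R/F1 %.4f/%.4f/%.4f\n",
              x$n, x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Broom-style accessors for an evaluation report
#'
#' `tidy()` returns per-class one-vs-rest metrics; `glance()` a one-row
#' macro summary.
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @rdname tidy.eval_report
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, accuracy = x$accuracy,
                 macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1)
}

#' @method autoplot eval_report
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(rownames(object$confusion))) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}
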