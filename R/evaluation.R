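#' Confusion matrix
#'
#' @param y_true,y_pred integer class indices in 1..K (equal length).
#' @param K number of classes.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(y_true, y_pred, K) {
  y_true <- as.integer(y_true)
  y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (any(c(y_true, y_pred) < 1L) || any(c(y_true, y_pred) > K)) {
    stop("class index out of range 1..", K, call. = FALSE)
  }
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  cm
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Accuracy is the trace over the total. Sensitivity (TP / (TP + FN)) and
#' specificity (TN / (TN + FP)) are computed one-vs-rest per class and
#' macro-averaged with unweighted means; classes with no true instances
#' (resp. no negative instances) are excluded from the corresponding macro
#' mean rather than scored as zero.
#'
#' @param cm a square confusion matrix (rows = true, columns = predicted).
#' @return an `eval_report` list with `accuracy`, `sensitivity`,
#'   `specificity`, the per-class vectors, and the confusion matrix.
#' @export
eval_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || sum(cm) < 1) {
    stop("cm must be a square confusion matrix with at least one count",
         call. = FALSE)
  }
  total <- sum(cm)
  K <- nrow(cm)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  sens <- ifelse(tp + fn > 0, tp / (tp + fn), NA_real_)
  spec <- ifelse(tn + fp > 0, tn / (tn + fp), NA_real_)
  structure(list(accuracy = sum(tp) / total,
                 sensitivity = mean(sens, na.rm = TRUE),
                 specificity = mean(spec, na.rm = TRUE),
                 per_class_sensitivity = sens,
                 per_class_specificity = spec,
                 n = total, n_classes = K,
                 confusion = cm),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%d classes, n = %d): accuracy %.4f, macro sensitivity %.4f, macro specificity %.4f\n",
              x$n_classes, x$n, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Coarsen a confusion matrix between granularity levels
#'
#' The coarse matrix is `G %*% cm %*% t(G)` for the 0/1 granule-membership
#' matrix G; total count is preserved.
#'
#' @param cm confusion matrix at `from_level`.
#' @param from_level,to_level granularity levels as in [coarsen()].
#' @return confusion matrix at `to_level`.
#' @export
coarsen_confusion <- function(cm, from_level, to_level) {
  G <- granule_matrix(from_level, to_level)
  if (ncol(G) != nrow(cm)) {
    stop("confusion matrix size does not match ", from_level, call. = FALSE)
  }
  G %*% as.matrix(cm) %*% t(G)
}

#' Evaluate a classifier on a test window set
#'
#' Returns the fine-level report and, when requested, a coarsened
#' primary-category (4-class) report obtained by summing predicted
#' probability mass over each granule before taking the argmax.
#'
#' @param model a `convmixer_model` or `dense_head`.
#' @param test_windows a `window_set` (ignored for a `dense_head`).
#' @param test_labels integer class indices at `level`, one per test window.
#' @param level granularity level of the model's classes.
#' @param test_features standardised feature matrix (needed for fusion
#'   models and dense heads).
#' @param report_coarsened also return the coarse (4-class) report.
#' @return an `eval_report`, or a list `list(fine = ..., coarse = ...)` when
#'   `report_coarsened` is `TRUE`.
#' @export
evaluate_model <- function(model, test_windows, test_labels, level,
                           test_features = NULL, report_coarsened = FALSE) {
  level <- match.arg(level, GRANULARITY_LEVELS)
  K <- n_classes(level)
  pr <- if (inherits(model, "dense_head")) {
    if (model$n_classes != K) {
      stop("model has ", model$n_classes, " classes but level ", level,
           " has ", K, call. = FALSE)
    }
    predict_dense_head(model, test_features)
  } else {
    if (model$config$n_classes != K) {
      stop("model has ", model$config$n_classes, " classes but level ",
           level, " has ", K, call. = FALSE)
    }
    predict_convmixer(model, test_windows, test_features)
  }
  fine <- eval_metrics(confusion_matrix(test_labels, pr$class, K))
  if (!report_coarsened) return(fine)
  cp <- coarsen_probabilities(pr$prob, level, "coarse")
  coarse_pred <- max.col(cp, ties.method = "first")
  coarse_true <- coarsen(test_labels, level, "coarse")
  coarse <- eval_metrics(confusion_matrix(coarse_true, coarse_pred, 4L))
  list(fine = fine, coarse = coarse)
}

#' Feature-only baseline classifiers (SVM, random forest, LDA)
#'
#' Fits the three classic baselines on the standardised 16-dimensional
#' handcrafted feature vectors via their established implementations
#' (\pkg{e1071}, \pkg{randomForest}, \pkg{MASS}) with library defaults, and
#' scores them with the same metric set as the deep model.
#'
#' @param train_features,train_labels training features (rows = windows) and
#'   class indices 1..K.
#' @param test_features,test_labels held-out split scored in the reports.
#' @param K number of classes.
#' @param seed seed for the stochastic learners.
#' @return named list of `eval_report`s (`svm`, `random_forest`, `lda`).
#' @export
run_baselines <- function(train_features, train_labels,
                          test_features, test_labels, K, seed = 1L) {
  ytr <- factor(as.integer(train_labels), levels = seq_len(K))
  if (length(unique(train_labels)) < 2) {
    stop("training split is degenerate (single class)", call. = FALSE)
  }
  tr <- as.data.frame(as.matrix(train_features))
  te <- as.data.frame(as.matrix(test_features))
  names(te) <- names(tr)
  reports <- list()
  withr::with_seed(as.integer(seed), {
    fit_svm <- e1071::svm(tr, ytr)
    reports$svm <- as.integer(as.character(predict(fit_svm, te)))
    fit_rf <- randomForest::randomForest(tr, ytr)
    reports$random_forest <- as.integer(as.character(predict(fit_rf, te)))
    fit_lda <- MASS::lda(tr, grouping = ytr)
    reports$lda <- as.integer(as.character(predict(fit_lda, te)$class))
  })
  lapply(reports, function(pred) {
    eval_metrics(confusion_matrix(test_labels, pred, K))
  })
}

#' Write an evaluation report to disk
#'
#' Metrics go to `<prefix>_metrics.json`, the confusion matrix to
#' `<prefix>_confusion.csv`, and (optionally) a heatmap of the confusion
#' matrix to `<prefix>_confusion.png`.
#'
#' @param report an `eval_report`.
#' @param prefix output path prefix.
#' @param png also render the heatmap.
#' @export
write_eval_report <- function(report, prefix, png = FALSE) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(accuracy = report$accuracy, sensitivity = report$sensitivity,
         specificity = report$specificity,
         per_class_sensitivity = report$per_class_sensitivity,
         per_class_specificity = report$per_class_specificity,
         n = report$n, n_classes = report$n_classes),
    paste0(prefix, "_metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$confusion, paste0(prefix, "_confusion.csv"),
                   row.names = FALSE)
  if (png) {
    grDevices::png(paste0(prefix, "_confusion.png"), width = 600, height = 600)
    plot_confusion(report$confusion)
    grDevices::dev.off()
  }
  invisible(report)
}

#' Heatmap of a confusion matrix
#'
#' True classes on the vertical axis (top to bottom), predicted on the
#' horizontal, with counts overlaid.
#'
#' @param cm confusion matrix.
#' @param main plot title.
#' @export
plot_confusion <- function(cm, main = "Confusion matrix") {
  cm <- as.matrix(cm)
  K <- nrow(cm)
  graphics::image(seq_len(K), seq_len(K), t(cm[K:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  xlab = "predicted", ylab = "true", axes = FALSE, main = main)
  graphics::axis(1, at = seq_len(K))
  graphics::axis(2, at = seq_len(K), labels = K:1)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    graphics::text(j, K + 1 - i, cm[i, j], cex = 0.7)
  }
  invisible(cm)
}
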