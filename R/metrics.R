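#' Binary classification metrics from label vectors
#'
#' Builds the 2x2 confusion matrix (rows = true class, columns = predicted)
#' and derives accuracy, sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' precision = TP/(TP+FP) and F1, all with respect to the positive class
#' (default `"Tumor"`).
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive the positive class.
#' @return object of class `raman_metrics`: list with `confusion` (2x2 count
#'   matrix), `accuracy`, `sensitivity`, `specificity`, `precision`, `f1`,
#'   `n`.
#' @export
compute_metrics <- function(y_true, y_pred, positive = "Tumor") {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred))
    stop("`y_true` and `y_pred` must have the same length")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  classes <- c(setdiff(unique(c(y_true, y_pred, positive)), positive), positive)
  if (length(classes) != 2) stop("exactly two classes are required")
  negative <- classes[1]
  tp <- sum(y_true == positive & y_pred == positive)
  tn <- sum(y_true == negative & y_pred == negative)
  fp <- sum(y_true == negative & y_pred == positive)
  fn <- sum(y_true == positive & y_pred == negative)
  confusion <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                      dimnames = list(true = c(negative, positive),
                                      predicted = c(negative, positive)))
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  structure(list(confusion = confusion,
                 accuracy = (tp + tn) / length(y_true),
                 sensitivity = recall,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
                 precision = precision,
                 f1 = f_score(precision, recall),
                 n = length(y_true), positive = positive),
            class = "raman_metrics")
}

#' Confusion-count constructor for worked examples
#'
#' Builds the same metrics object directly from the four confusion counts
#' (true negatives, false positives, false negatives, true positives).
#'
#' @param tn,fp,fn,tp non-negative integer counts.
#' @param positive,negative class names.
#' @return a `raman_metrics` object, as [compute_metrics()].
#' @export
metrics_from_counts <- function(tn, fp, fn, tp, positive = "Tumor",
                                negative = "Non-Tumor") {
  compute_metrics(rep(c(negative, negative, positive, positive),
                      c(tn, fp, fn, tp)),
                  rep(c(negative, positive, negative, positive),
                      c(tn, fp, fn, tp)),
                  positive = positive)
}

#' Harmonic mean of precision and recall
#' @param precision,recall fractions in `[0, 1]`.
#' @return the F-score, `NA` if undefined.
#' @export
f_score <- function(precision, recall) {
  ifelse(is.na(precision) | is.na(recall) | (precision + recall) == 0,
         NA_real_, 2 * precision * recall / (precision + recall))
}

#' @export
print.raman_metrics <- function(x, digits = 2, ...) {
  cat("Confusion matrix (true x predicted):\n")
  print(x$confusion)
  cat(sprintf(paste0("accuracy    %.*f%%\nsensitivity %.*f%%\n",
                     "specificity %.*f%%\nprecision   %.*f%%\nF1          %.*f%%\n"),
              digits, 100 * x$accuracy, digits, 100 * x$sensitivity,
              digits, 100 * x$specificity, digits, 100 * x$precision,
              digits, 100 * x$f1))
  invisible(x)
}

#' Cross-validation configuration
#'
#' @param k number of folds (>= 2, default 5).
#' @param split_mode `"spectrum"` (random stratified split of spectra) or
#'   `"cell"` (whole cells assigned to folds, so no cell leaks across folds).
#' @param seed integer seed or `NULL`.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(k = 5, split_mode = c("spectrum", "cell"), seed = NULL) {
  split_mode <- match.arg(split_mode)
  stopifnot(k >= 2)
  structure(list(k = as.integer(k), split_mode = split_mode, seed = seed),
            class = "cv_config")
}

#' Fold assignment for cross-validation
#'
#' Stratified by class in `"spectrum"` mode; in `"cell"` mode whole cells are
#' assigned to folds so no cell contributes spectra to both training and
#' validation.
#'
#' @param labels class labels.
#' @param cv a [cv_config()].
#' @param cell_ids cell identifiers (required for `split_mode = "cell"`).
#' @return integer vector of fold ids in `1:k`.
#' @export
cv_folds <- function(labels, cv = cv_config(), cell_ids = NULL) {
  n <- length(labels)
  with_seed(cv$seed, {
    folds <- integer(n)
    if (cv$split_mode == "spectrum") {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        folds[idx] <- sample(rep_len(seq_len(cv$k), length(idx)))
      }
    } else {
      if (is.null(cell_ids)) stop("`cell_ids` required for cell-level splits")
      cells <- unique(cell_ids)
      cell_class <- labels[match(cells, cell_ids)]
      cell_fold <- integer(length(cells))
      for (cl in unique(cell_class)) {
        idx <- which(cell_class == cl)
        cell_fold[idx] <- sample(rep_len(seq_len(cv$k), length(idx)))
      }
      folds <- cell_fold[match(cell_ids, cells)]
    }
    folds
  })
}

#' Stratified train/test split
#'
#' Random split preserving the class ratio within one spectrum per class.
#'
#' @param labels class labels.
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed or `NULL`.
#' @return list with integer vectors `train` and `test`.
#' @export
train_test_split <- function(labels, test_fraction = 0.2, seed = NULL) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  with_seed(seed, {
    test <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      test <- c(test, sample(idx, round(test_fraction * length(idx))))
    }
    list(train = setdiff(seq_along(labels), test), test = sort(test))
  })
}

#' Learning curve by k-fold cross-validation
#'
#' For each training size, fits the model on the first `n_train` samples of
#' each fold's training split and records training and validation accuracy,
#' averaged over folds.
#'
#' @param builder function `(x, labels) -> model`; the model must work with
#'   [stats::predict()] returning labels.
#' @param x numeric feature matrix (rows = samples).
#' @param labels class labels.
#' @param train_sizes increasing vector of training sizes.
#' @param cv a [cv_config()].
#' @return data frame of class `learning_curve`: `n_train`, `train_acc`,
#'   `cv_acc`.
#' @export
learning_curve <- function(builder, x, labels, train_sizes,
                           cv = cv_config()) {
  stopifnot(all(diff(train_sizes) > 0))
  folds <- cv_folds(labels, cv)
  max_train <- length(labels) - max(table(folds))
  if (max(train_sizes) > max_train)
    stop("`train_sizes` exceeds the available training-split size")
  # shuffle each fold's training indices once so size-m subsets are random
  # (and class-mixed) rather than index-ordered
  train_pool <- with_seed(cv$seed,
                          lapply(seq_len(cv$k),
                                 function(f) sample(which(folds != f))))
  out <- lapply(train_sizes, function(m) {
    tr_acc <- cv_acc <- numeric(cv$k)
    for (f in seq_len(cv$k)) {
      tr <- train_pool[[f]][seq_len(m)]
      te <- which(folds == f)
      fit <- builder(x[tr, , drop = FALSE], labels[tr])
      tr_acc[f] <- mean(predict(fit, x[tr, , drop = FALSE]) == labels[tr])
      cv_acc[f] <- mean(predict(fit, x[te, , drop = FALSE]) == labels[te])
    }
    data.frame(n_train = m, train_acc = mean(tr_acc), cv_acc = mean(cv_acc))
  })
  out <- do.call(rbind, out)
  class(out) <- c("learning_curve", "data.frame")
  out
}

#' @export
plot.learning_curve <- function(x, ...) {
  graphics::plot(x$n_train, x$train_acc, type = "b", ylim = c(0, 1),
                 xlab = "Training spectra", ylab = "Accuracy", ...)
  graphics::lines(x$n_train, x$cv_acc, type = "b", col = "red3")
  graphics::legend("bottomright", c("training", "cross-validation"),
                   col = c("black", "red3"), lty = 1, bty = "n")
  invisible(x)
}
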