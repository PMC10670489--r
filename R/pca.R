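#' Principal component analysis of a spectrum set
#'
#' PCA on the covariance matrix of mean-centered intensities (no scaling),
#' i.e. the eigendecomposition of `cov(X)`, computed stably through the
#' singular value decomposition. Components are sorted by decreasing
#' variance.
#'
#' @param x numeric matrix (rows = spectra) or a [raman_set()].
#' @return object of class `raman_pca`: `mean_spectrum`, `loadings`
#'   (orthonormal columns), `sdev`, `explained_variance_pct` (sums to 100
#'   over all components), `scores` of the training data.
#' @export
pca_fit <- function(x) {
  if (inherits(x, "raman_set")) x <- x$intensities
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("at least two spectra are required")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  structure(list(mean_spectrum = pc$center, loadings = pc$rotation,
                 sdev = pc$sdev,
                 explained_variance_pct = 100 * ev / sum(ev),
                 scores = pc$x),
            class = "raman_pca")
}

#' @export
print.raman_pca <- function(x, ...) {
  k <- min(3, length(x$sdev))
  cat(sprintf("<raman_pca> %d components; PC1-%d explain %.1f%% of variance\n",
              length(x$sdev), k, sum(x$explained_variance_pct[seq_len(k)])))
  invisible(x)
}

#' @export
predict.raman_pca <- function(object, newdata, n_pc = NULL, ...) {
  if (inherits(newdata, "raman_set")) newdata <- newdata$intensities
  newdata <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  sc <- sweep(newdata, 2, object$mean_spectrum) %*% object$loadings
  if (!is.null(n_pc)) sc <- sc[, seq_len(n_pc), drop = FALSE]
  sc
}

#' @export
plot.raman_pca <- function(x, pcs = c(1, 2), labels = NULL, ...) {
  sc <- x$scores[, pcs, drop = FALSE]
  col <- if (is.null(labels)) "black" else as.integer(factor(labels)) + 1L
  graphics::plot(sc[, 1], sc[, 2], col = col, pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", pcs[1],
                                x$explained_variance_pct[pcs[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", pcs[2],
                                x$explained_variance_pct[pcs[2]]), ...)
  if (!is.null(labels))
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))) + 1L, pch = 19,
                     bty = "n")
  invisible(x)
}

#' PCA-LDA with leave-one-out selection of the component count
#'
#' Fits PCA once on the full data, then for each candidate number of leading
#' components computes the leave-one-out cross-validated error of an LDA on
#' the scores. The count minimizing the LOOCV error is selected (smallest
#' count on ties) and the final PCA + LDA model is refitted on all data. The
#' cumulative explained variance of the selected components is reported
#' alongside.
#'
#' @param x feature matrix or preprocessed [raman_set()].
#' @param labels class labels (from the set if omitted).
#' @param pc_counts candidate component counts (default `seq(5, 60, by = 5)`,
#'   truncated to the available components).
#' @param shrinkage LDA shrinkage used on the scores (default `"none"`).
#' @return object of class `raman_pca_lda`: the fitted `pca` and `lda`,
#'   `n_pc`, `cum_var_pct`, and the LOOCV error table `loocv`.
#' @export
pca_lda_loocv <- function(x, labels = NULL, pc_counts = seq(5, 60, by = 5),
                          shrinkage = "none") {
  pp_cfg <- NULL
  if (inherits(x, "raman_set")) {
    if (is.null(labels)) labels <- set_labels(x)
    pp_cfg <- attr(x, "pp_config")
    x <- x$intensities
  }
  x <- as.matrix(x); labels <- as.character(labels)
  n <- nrow(x)
  pca <- pca_fit(x)
  avail <- sum(pca$sdev > pca$sdev[1] * 1e-8)
  pc_counts <- pc_counts[pc_counts <= min(avail, n - 2)]
  if (length(pc_counts) == 0) stop("no candidate component count is feasible")
  scores <- pca$scores
  err <- vapply(pc_counts, function(m) {
    sc <- scores[, seq_len(m), drop = FALSE]
    wrong <- 0L
    for (i in seq_len(n)) {
      fit <- lda_fit(sc[-i, , drop = FALSE], labels[-i],
                     shrinkage = shrinkage)
      wrong <- wrong + (predict(fit, sc[i, , drop = FALSE]) != labels[i])
    }
    wrong / n
  }, numeric(1))
  n_pc <- pc_counts[which.min(err)]  # smallest count on ties
  lda <- lda_fit(scores[, seq_len(n_pc), drop = FALSE], labels,
                 shrinkage = shrinkage)
  structure(list(pca = pca, lda = lda, n_pc = n_pc,
                 cum_var_pct = sum(pca$explained_variance_pct[seq_len(n_pc)]),
                 loocv = data.frame(n_pc = pc_counts, loocv_error = err),
                 pp_config = pp_cfg),
            class = "raman_pca_lda")
}

#' @export
predict.raman_pca_lda <- function(object, newdata,
                                  type = c("label", "prob", "score"), ...) {
  sc <- predict(object$pca, newdata, n_pc = object$n_pc)
  predict(object$lda, sc, type = match.arg(type))
}

#' @export
print.raman_pca_lda <- function(x, ...) {
  cat(sprintf("<raman_pca_lda> %d PCs selected (%.1f%% cumulative variance), LOOCV error %.3f\n",
              x$n_pc, x$cum_var_pct,
              x$loocv$loocv_error[x$loocv$n_pc == x$n_pc]))
  invisible(x)
}
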