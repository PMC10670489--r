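# Ledoit-Wolf optimal shrinkage intensity toward a scaled identity target,
# computed on the within-class centered observations.
ledoit_wolf_gamma <- function(Xc, S) {
  n <- nrow(Xc); p <- ncol(Xc)
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  xx <- rowSums(Xc^2)
  xsx <- rowSums((Xc %*% S) * Xc)
  b2 <- (sum(xx^2) - 2 * sum(xsx) + n * sum(S^2)) / (n^2 * p)
  b2 <- min(b2, d2)
  if (d2 <= 0) 0 else b2 / d2
}

resolve_shrinkage <- function(shrinkage, Xc, S) {
  if (identical(shrinkage, "auto")) return(ledoit_wolf_gamma(Xc, S))
  if (identical(shrinkage, "none")) return(0)
  g <- suppressWarnings(as.numeric(shrinkage))
  if (is.na(g) || g < 0 || g > 1)
    stop("`shrinkage` must be \"none\", \"auto\" or a number in [0, 1]")
  g
}

#' Two-class linear discriminant analysis with covariance shrinkage
#'
#' Fits a linear discriminant on spectra (or any feature matrix): pooled
#' within-class covariance, optionally shrunk toward a scaled identity
#' (`S* = (1 - gamma) S + gamma (tr S / p) I`), class priors from training
#' frequencies or uniform. Shrinkage makes the fit well-posed when the number
#' of spectral channels exceeds the number of spectra; `shrinkage = "auto"`
#' uses the Ledoit-Wolf intensity, `"none"` falls back to a pseudo-inverse
#' when the pooled covariance is singular.
#'
#' @param x numeric matrix (rows = spectra) or a [raman_set()].
#' @param labels class labels (taken from `x$meta$label` for a set).
#' @param shrinkage `"none"`, `"auto"` (Ledoit-Wolf) or a number in `[0, 1]`.
#' @param priors `"empirical"` (training frequencies) or `"uniform"`.
#' @param positive the class reported as positive (default `"Tumor"`).
#' @return object of class `raman_lda` with discriminant vector `w`,
#'   threshold `b` (predict positive when `x.w > b`), and fit metadata.
#' @export
lda_fit <- function(x, labels = NULL, shrinkage = "none",
                    priors = c("empirical", "uniform"), positive = "Tumor") {
  priors <- match.arg(priors)
  pp_cfg <- NULL
  if (inherits(x, "raman_set")) {
    if (is.null(labels)) labels <- set_labels(x)
    pp_cfg <- attr(x, "pp_config")
    x <- x$intensities
  }
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- unique(labels)
  if (length(classes) != 2) stop("exactly two classes are required")
  if (!positive %in% classes) positive <- classes[2]
  negative <- setdiff(classes, positive)
  pos <- labels == positive
  m1 <- colMeans(x[pos, , drop = FALSE])
  m0 <- colMeans(x[!pos, , drop = FALSE])
  Xc <- x
  Xc[pos, ] <- sweep(x[pos, , drop = FALSE], 2, m1)
  Xc[!pos, ] <- sweep(x[!pos, , drop = FALSE], 2, m0)
  n <- nrow(x); p <- ncol(x)
  S <- crossprod(Xc) / (n - 2)
  gamma <- resolve_shrinkage(shrinkage, Xc, S)
  if (gamma > 0) {
    mu <- sum(diag(S)) / p
    S <- (1 - gamma) * S
    diag(S) <- diag(S) + gamma * mu
  }
  delta <- m1 - m0
  w <- tryCatch(solve(S, delta), error = function(e) {
    eg <- eigen(S, symmetric = TRUE)
    keep <- eg$values > max(eg$values) * 1e-10
    drop(eg$vectors[, keep, drop = FALSE] %*%
           ((crossprod(eg$vectors[, keep, drop = FALSE], delta)) /
              eg$values[keep]))
  })
  pr1 <- if (priors == "empirical") mean(pos) else 0.5
  b <- 0.5 * sum(w * (m1 + m0)) - log(pr1 / (1 - pr1))
  structure(list(w = w, b = b, means = rbind(m0, m1), gamma = gamma,
                 shrinkage = shrinkage, priors = priors,
                 classes = c(negative, positive), positive = positive,
                 n = n, p = p, pp_config = pp_cfg),
            class = "raman_lda")
}

#' @export
predict.raman_lda <- function(object, newdata,
                              type = c("label", "prob", "score"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "raman_set")) newdata <- newdata$intensities
  newdata <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1)
  score <- drop(newdata %*% object$w) - object$b
  switch(type,
         score = score,
         prob = stats::plogis(score),
         label = ifelse(score > 0, object$classes[2], object$classes[1]))
}

#' @export
print.raman_lda <- function(x, ...) {
  cat(sprintf("<raman_lda> %d features, n = %d, shrinkage = %s (gamma = %.4g), priors = %s\n",
              x$p, x$n, as.character(x$shrinkage), x$gamma, x$priors))
  invisible(x)
}

#' @export
coef.raman_lda <- function(object, ...) object$w

#' @export
summary.raman_lda <- function(object, ...) {
  cat("Two-class LDA\n")
  print(object)
  cat(sprintf("  classes: %s (negative) vs %s (positive)\n",
              object$classes[1], object$classes[2]))
  invisible(object)
}

#' Default hyper-parameter grid for LDA tuning
#'
#' The standard tunable surface of a shrinkage LDA: shrinkage intensity
#' (`none`, Ledoit-Wolf `auto`, and fixed values 0.1-0.9) crossed with
#' empirical or uniform class priors.
#'
#' @return data frame with columns `shrinkage` (character) and `priors`.
#' @export
default_lda_grid <- function() {
  expand.grid(shrinkage = c("none", "auto", "0.1", "0.3", "0.5", "0.7", "0.9"),
              priors = c("empirical", "uniform"),
              stringsAsFactors = FALSE)
}

#' Grid-search hyper-parameter tuning of LDA
#'
#' Exhaustively evaluates every grid point by k-fold cross-validated
#' accuracy, then refits the best configuration (ties broken by first-in-grid
#' order) on the full data.
#'
#' @param x feature matrix or [raman_set()].
#' @param labels class labels (from the set if omitted).
#' @param grid data frame with columns `shrinkage`, `priors`; see
#'   [default_lda_grid()].
#' @param cv a [cv_config()].
#' @param cell_ids cell ids for `split_mode = "cell"`.
#' @return a `raman_lda` model with an extra element `tuning` (the CV table
#'   and the selected row).
#' @export
tune_lda_grid <- function(x, labels = NULL, grid = default_lda_grid(),
                          cv = cv_config(), cell_ids = NULL) {
  if (inherits(x, "raman_set")) {
    if (is.null(labels)) labels <- set_labels(x)
    if (is.null(cell_ids)) cell_ids <- x$meta$cell_id
    pp_cfg <- attr(x, "pp_config")
    x <- x$intensities
  } else pp_cfg <- NULL
  if (nrow(grid) == 0) stop("`grid` must be non-empty")
  folds <- cv_folds(labels, cv, cell_ids)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(cv$k)) {
      tr <- folds != f
      fit <- lda_fit(x[tr, , drop = FALSE], labels[tr],
                     shrinkage = grid$shrinkage[g], priors = grid$priors[g])
      correct <- correct +
        sum(predict(fit, x[!tr, , drop = FALSE]) == labels[!tr])
    }
    acc[g] <- correct / length(labels)
  }
  best <- which.max(acc)  # first index on ties
  model <- lda_fit(x, labels, shrinkage = grid$shrinkage[best],
                   priors = grid$priors[best])
  model$pp_config <- pp_cfg
  model$tuning <- list(grid = cbind(grid, cv_accuracy = acc), best = best,
                       cv = cv)
  class(model) <- c("raman_tuned_lda", class(model))
  model
}

#' @export
print.raman_tuned_lda <- function(x, ...) {
  b <- x$tuning$best
  cat(sprintf("<raman_tuned_lda> best of %d grid points (CV accuracy %.3f)\n",
              nrow(x$tuning$grid), x$tuning$grid$cv_accuracy[b]))
  NextMethod()
}
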