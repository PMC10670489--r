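test_that("PCA matches a dense covariance eigendecomposition", {
  set.seed(3)
  X <- matrix(rnorm(10 * 20), 10, 20)
  p <- pca_fit(X)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  expect_equal(p$sdev^2, ev[seq_along(p$sdev)], tolerance = 1e-8)
  expect_equal(sum(p$explained_variance_pct), 100, tolerance = 1e-6)
  expect_true(all(diff(p$explained_variance_pct) <= 1e-12))
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # full reconstruction
  rec <- sweep(p$scores %*% t(p$loadings), 2, p$mean_spectrum, "+")
  expect_lt(max(abs(rec - X)), 1e-8)
})

test_that("exactly planar data has exactly two nonzero eigenvalues", {
  set.seed(5)
  basis <- qr.Q(qr(matrix(rnorm(15 * 2), 15, 2)))
  X <- matrix(rnorm(30 * 2), 30, 2) %*% t(basis)
  p <- pca_fit(X)
  expect_equal(sum(p$sdev > p$sdev[1] * 1e-8), 2)
  expect_error(pca_fit(X[1, , drop = FALSE]), "two spectra")
})

test_that("LDA separates well-separated classes and chances identical ones", {
  set.seed(6)
  n <- 200
  lab <- rep(c("Non-Tumor", "Tumor"), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4)
  X[lab == "Tumor", 1] <- X[lab == "Tumor", 1] + 10
  sp <- train_test_split(lab, 0.3, seed = 1)
  fit <- lda_fit(X[sp$train, ], lab[sp$train])
  expect_equal(mean(predict(fit, X[sp$test, ]) == lab[sp$test]), 1)

  n <- 1000
  lab <- rep(c("Non-Tumor", "Tumor"), each = n / 2)
  X <- matrix(rnorm(n * 4), n, 4)  # identical class distributions
  sp <- train_test_split(lab, 0.5, seed = 2)
  fit <- lda_fit(X[sp$train, ], lab[sp$train])
  acc <- mean(predict(fit, X[sp$test, ]) == lab[sp$test])
  expect_gt(acc, 0.45); expect_lt(acc, 0.55)
  expect_error(lda_fit(X, rep("Tumor", n)), "two classes")
})

test_that("the decision boundary crosses the inter-mean segment once", {
  set.seed(8)
  lab <- rep(c("Non-Tumor", "Tumor"), each = 50)
  X <- matrix(rnorm(100 * 3), 100, 3)
  X[lab == "Tumor", ] <- X[lab == "Tumor", ] + 2
  fit <- lda_fit(X, lab)
  m0 <- colMeans(X[lab == "Non-Tumor", ]); m1 <- colMeans(X[lab == "Tumor", ])
  tt <- seq(0, 1, length.out = 201)
  scores <- predict(fit, t(vapply(tt, function(a) (1 - a) * m0 + a * m1,
                                  numeric(3))), type = "score")
  expect_equal(sum(diff(scores > 0) != 0), 1)  # exactly one sign change
})

test_that("shrinkage LDA agrees with the classical solution on easy data", {
  set.seed(10)
  lab <- rep(c("Non-Tumor", "Tumor"), each = 60)
  X <- matrix(rnorm(120 * 5), 120, 5)
  X[lab == "Tumor", 1:2] <- X[lab == "Tumor", 1:2] + 1.5
  fit <- lda_fit(X, lab, shrinkage = "none")
  ref <- MASS::lda(X, grouping = lab)
  Xnew <- matrix(rnorm(80 * 5), 80, 5) + 0.75
  expect_equal(as.character(predict(fit, Xnew)),
               as.character(predict(ref, Xnew)$class))
})

test_that("grid search selects at least as well as the default LDA", {
  set.seed(12)
  lab <- rep(c("Non-Tumor", "Tumor"), each = 30)
  X <- matrix(rnorm(60 * 40), 60, 40)
  X[lab == "Tumor", 1:3] <- X[lab == "Tumor", 1:3] + 0.8
  cv <- cv_config(k = 5, seed = 4)
  one <- tune_lda_grid(X, lab, grid = data.frame(shrinkage = "0.3",
                                                 priors = "empirical"),
                       cv = cv)
  direct <- lda_fit(X, lab, shrinkage = 0.3)
  expect_equal(one$w, direct$w)
  expect_equal(one$b, direct$b)

  tuned <- tune_lda_grid(X, lab, cv = cv)
  grid <- tuned$tuning$grid
  default_row <- which(grid$shrinkage == "none" & grid$priors == "empirical")
  expect_gte(grid$cv_accuracy[tuned$tuning$best],
             grid$cv_accuracy[default_row])
  expect_error(tune_lda_grid(X, lab, grid = data.frame()), "non-empty")
})

test_that("tuning beats plain LDA on noisy high-dimensional data", {
  deltas <- vapply(1:5, function(s) {
    set.seed(100 + s)
    n <- 60; p <- 150
    lab <- rep(c("Non-Tumor", "Tumor"), each = n / 2)
    X <- matrix(rnorm(n * p), n, p)
    X[lab == "Tumor", 1:10] <- X[lab == "Tumor", 1:10] + 0.5
    Xt <- matrix(rnorm(200 * p), 200, p)
    labt <- rep(c("Non-Tumor", "Tumor"), each = 100)
    Xt[labt == "Tumor", 1:10] <- Xt[labt == "Tumor", 1:10] + 0.5
    plain <- lda_fit(X, lab, shrinkage = "none")
    tuned <- tune_lda_grid(X, lab, cv = cv_config(k = 5, seed = s))
    mean(predict(tuned, Xt) == labt) - mean(predict(plain, Xt) == labt)
  }, numeric(1))
  expect_gt(mean(deltas), 0)
})

test_that("LOOCV component selection prefers the smallest sufficient count", {
  set.seed(14)
  n <- 60
  lab <- rep(c("Non-Tumor", "Tumor"), each = n / 2)
  # discriminative structure confined to the two leading PCs
  X <- cbind(matrix(rnorm(n * 2, sd = 4), n, 2),
             matrix(rnorm(n * 28, sd = 0.05), n, 28))
  X[lab == "Tumor", 1] <- X[lab == "Tumor", 1] + 20
  fit <- pca_lda_loocv(X, lab, pc_counts = c(2, 5, 10))
  expect_equal(fit$n_pc, 2)
  err <- fit$loocv$loocv_error
  expect_lte(err[fit$loocv$n_pc == fit$n_pc], err[1])
  expect_lte(err[fit$loocv$n_pc == fit$n_pc], err[length(err)])
  expect_true(fit$cum_var_pct > 0 && fit$cum_var_pct <= 100)
  expect_equal(as.character(predict(fit, X)), lab)  # separable training data
})

test_that("learning curves have the declared shape and saturate upward", {
  registerS3method("predict", "memorizer", function(object, newdata, ...) {
    key <- apply(round(newdata, 10), 1, paste, collapse = ",")
    idx <- match(key, object$keys)
    ifelse(is.na(idx), object$fallback, object$labels[idx])
  }, envir = asNamespace("stats"))
  set.seed(16)
  n <- 80
  lab <- rep(c("Non-Tumor", "Tumor"), each = n / 2)
  X <- matrix(rnorm(n * 3), n, 3)
  X[lab == "Tumor", 1] <- X[lab == "Tumor", 1] + 3
  memorize <- function(x, labels)
    structure(list(keys = apply(round(x, 10), 1, paste, collapse = ","),
                   labels = labels, fallback = labels[1]),
              class = "memorizer")
  lc <- learning_curve(memorize, X, lab, train_sizes = c(10, 20, 40),
                       cv = cv_config(k = 4, seed = 5))
  expect_equal(nrow(lc), 3)
  expect_true(all(lc$train_acc == 1))

  lc2 <- learning_curve(function(x, l) lda_fit(x, l), X, lab,
                        train_sizes = c(10, 30, 50),
                        cv = cv_config(k = 4, seed = 6))
  expect_equal(nrow(lc2), 3)
  expect_gte(lc2$cv_acc[3], lc2$cv_acc[1] - 0.05)
  expect_error(learning_curve(function(x, l) lda_fit(x, l), X, lab,
                              train_sizes = c(10, 1000)), "exceeds")
})

test_that("metrics agree with a brute-force counting oracle", {
  set.seed(18)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    yt <- sample(c("Non-Tumor", "Tumor"), n, replace = TRUE)
    yp <- sample(c("Non-Tumor", "Tumor"), n, replace = TRUE)
    if (length(unique(c(yt, yp))) < 2) next
    m <- compute_metrics(yt, yp)
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (yt[j] == "Tumor" && yp[j] == "Tumor") tp <- tp + 1
      if (yt[j] == "Tumor" && yp[j] == "Non-Tumor") fn <- fn + 1
      if (yt[j] == "Non-Tumor" && yp[j] == "Tumor") fp <- fp + 1
      if (yt[j] == "Non-Tumor" && yp[j] == "Non-Tumor") tn <- tn + 1
    }
    expect_equal(sum(m$confusion), n)
    expect_equal(m$accuracy, (tp + tn) / n)
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
  }
  perfect <- compute_metrics(c("Tumor", "Non-Tumor"), c("Tumor", "Non-Tumor"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  expect_error(compute_metrics(character(0), character(0)), "empty")
})

test_that("splits are stratified and cell-grouped folds do not leak", {
  lab <- rep(c("Non-Tumor", "Tumor"), c(177, 181))
  sp <- train_test_split(lab, 0.2, seed = 9)
  for (cl in unique(lab)) {
    target <- 0.2 * sum(lab == cl)
    expect_lte(abs(sum(lab[sp$test] == cl) - target), 1)
  }
  expect_equal(sort(c(sp$train, sp$test)), seq_along(lab))

  cells <- rep(sprintf("c%02d", 1:40), each = 5)
  lab2 <- rep(c("Non-Tumor", "Tumor"), each = 100)
  folds <- cv_folds(lab2, cv_config(k = 5, split_mode = "cell", seed = 3),
                    cell_ids = cells)
  for (cl in unique(cells))
    expect_equal(length(unique(folds[cells == cl])), 1)
})
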