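make_labeled_set <- function(X, labels) {
  raman_set(seq_len(ncol(X)) + 599, X,
            data.frame(label = labels, stage = "preprocessed"))
}

test_that("data lying in the model subspace has zero Q-residuals", {
  set.seed(4)
  n <- 40; p <- 60; A <- 3
  scores <- matrix(rnorm(n * A), n, A)
  load <- qr.Q(qr(matrix(rnorm(p * A), p, A)))
  labels <- rep(c("Tumor", "Non-Tumor"), each = n / 2)
  scores[, 1] <- scores[, 1] + ifelse(labels == "Tumor", 2, -2)
  X <- scores %*% t(load)
  m <- fit_outlier_model(make_labeled_set(X, labels), n_components = A)
  expect_lt(max(m$q_stats), 1e-20 * max(rowSums(X^2)))
  expect_true(all(m$t2_stats >= 0))
  expect_error(fit_outlier_model(make_labeled_set(X, labels),
                                 n_components = n), "smaller")
})

test_that("T2 flags about 5% of multivariate-normal null data", {
  set.seed(7)
  n <- 2000; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  labels <- sample(c("Tumor", "Non-Tumor"), n, replace = TRUE)
  m <- fit_outlier_model(make_labeled_set(X, labels), n_components = 5)
  rate <- mean(m$t2_stats > m$t2_limit)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("a gross spike is the most anomalous spectrum in the set", {
  cfg <- sim_config(n_cells_per_class = 5, spectra_per_cell = 5,
                    axis = tiny_axis(), seed = 12)
  raw <- generate_dataset(cfg)
  m <- fit_outlier_model(preprocess_spectra(raw), n_components = 5)
  i_spike <- 17
  raw$intensities[i_spike, 150] <- raw$intensities[i_spike, 150] +
    100 * max(abs(raw$intensities))
  pp <- preprocess_spectra(raw)
  # against a model of clean spectra the spike has the largest Q-residual
  fl <- flag_outliers(pp, m)
  expect_equal(which.max(attr(fl, "qc_report")$Q), i_spike)
  expect_true(fl$meta$outlier_flag[i_spike])
  # refitting with the spike included absorbs it into the score space, where
  # it surfaces as the most extreme Hotelling T2 (outlier masking moves the
  # signal between the two statistics; the union rule still flags it)
  m2 <- fit_outlier_model(pp, n_components = 5)
  expect_equal(which.max(m2$t2_stats), i_spike)
  expect_true(m2$q_stats[i_spike] > m2$q_limit ||
                m2$t2_stats[i_spike] > m2$t2_limit)
})

test_that("flagging rules nest and bookkeeping is conserved", {
  pipe <- study_pipeline()
  either <- flag_outliers(pipe$pp, pipe$model, rule = "either")
  both <- flag_outliers(pipe$pp, pipe$model, rule = "both")
  expect_true(all(which(both$meta$outlier_flag) %in%
                    which(either$meta$outlier_flag)))
  sm <- qc_summary(either)
  expect_equal(sm$retained, sm$n - sm$flagged)
  expect_equal(sm$n[sm$class == "Total"], n_spectra(pipe$pp))
  clean <- remove_outliers(either)
  expect_equal(n_spectra(clean),
               n_spectra(pipe$pp) - sum(either$meta$outlier_flag))
  # infinite limits flag nothing
  loose <- pipe$model
  loose$q_limit <- Inf; loose$t2_limit <- Inf
  expect_equal(sum(flag_outliers(pipe$pp, loose)$meta$outlier_flag), 0)
})

test_that("Q and T2 are invariant to spectrum ordering", {
  pp <- tiny_clean_set(seed = 13, n_cells = 4)
  m <- fit_outlier_model(pp, n_components = 3)
  set.seed(2)
  perm <- sample(n_spectra(pp))
  m2 <- fit_outlier_model(pp[perm], n_components = 3)
  expect_equal(m2$q_stats, m$q_stats[perm], tolerance = 1e-8)
  expect_equal(m2$t2_stats, m$t2_stats[perm], tolerance = 1e-8)
  expect_equal(m2$q_limit, m$q_limit, tolerance = 1e-8)
})

test_that("NIPALS scores agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(9)
  n <- 30; p <- 25; A <- 3
  X <- matrix(rnorm(n * p), n, p)
  y <- as.numeric(rowMeans(X[, 1:5]) + rnorm(n, sd = 0.2) > 0)
  X[, 1] <- X[, 1] + 2 * y
  fit <- ramancell:::nipals_pls1(X, y, A)
  ref <- mixOmics::pls(X, y, ncomp = A, scale = FALSE, mode = "regression")
  for (a in seq_len(A))
    expect_gt(abs(stats::cor(fit$scores[, a], ref$variates$X[, a])), 0.999)
})
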