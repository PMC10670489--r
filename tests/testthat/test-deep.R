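test_that("windowing produces equal non-overlapping slices", {
  w <- window_spectrum(seq_len(1200), k_s = 3)
  expect_equal(lengths(w$slices), rep(400, 3))
  expect_equal(unlist(w$slices), seq_len(1200))

  w2 <- window_spectrum(seq_len(1201), k_s = 3)
  expect_equal(lengths(w2$slices), rep(400, 3))
  expect_equal(unlist(w2$slices), seq_len(1200))  # one trailing point dropped

  w3 <- window_spectrum(seq_len(50), k_s = 1)
  expect_equal(w3$slices[[1]], seq_len(50))
  expect_error(window_spectrum(seq_len(50), k_s = 0), "k_s")
})

test_that("value augmentation is bounded and zero-mean", {
  slice <- sin(seq(0, 4 * pi, length.out = 100)) + 2
  set.seed(20)
  expect_equal(augment_value(slice, pct = 0), slice)
  for (i in 1:20) {
    a <- augment_value(slice, pct = 10)
    expect_true(all(abs(a - slice) <= 0.1 * abs(slice) + 1e-12))
  }
  acc <- rowMeans(replicate(1e4, augment_value(slice, pct = 10)))
  expect_lt(max(abs(acc - slice) / abs(slice)), 0.01)
})

test_that("frequency augmentation shifts peaks boundedly and reversibly", {
  x <- seq_len(200)
  slice <- exp(-(x - 120)^2 / 40)
  set.seed(21)
  expect_equal(augment_frequency(slice, pct = 0), slice)
  for (i in 1:20) {
    a <- augment_frequency(slice, pct = 10)
    expect_lte(abs(which.max(a) - 120), 0.1 * 200 + 1)
    expect_equal(length(a), 200)
  }
  smooth <- sin(x / 15) + 1.5
  d <- 7.3
  round_trip <- ramancell:::shift_slice(ramancell:::shift_slice(smooth, d), -d)
  interior <- 30:170
  expect_lt(max(abs(round_trip[interior] - smooth[interior])), 5e-3)
})

test_that("network configuration enforces the tuned ranges", {
  expect_error(net_config(n_layers = 30), "25 or 56")
  expect_error(net_config(learning_rate = 0.2), "learning_rate")
  expect_error(net_config(dropout = 0.5), "dropout")
  expect_error(net_config(reject_threshold = 1.5), "reject_threshold")
  expect_s3_class(net_config(), "net_config")
})

test_that("model builds are deterministic with a layer manifest", {
  m1 <- build_model(net_config(seed = 7), 1201)
  m2 <- build_model(net_config(seed = 7), 1201)
  expect_identical(m1$params, m2$params)
  expect_equal(nrow(m1$manifest), 25)
  m56 <- build_model(net_config(n_layers = 56, learning_rate = 0.01,
                                dropout = 0.2, seed = 7), 1201)
  expect_equal(nrow(m56$manifest), 56)
  expect_gt(m56$n_params, m1$n_params)
})

test_that("softmax outputs are probability vectors for any input", {
  m <- build_model(net_config(seed = 3), length(tiny_axis()))
  set.seed(22)
  X3 <- array(rnorm(7 * 3 * m$slice_len), c(7, 3, m$slice_len))
  probs <- predict(m, X3, type = "prob")
  expect_equal(rowSums(probs), rep(1, 7), tolerance = 1e-12)
  expect_true(all(probs >= 0))
})

test_that("the reject option behaves monotonically in the threshold", {
  m <- build_model(net_config(seed = 5), length(tiny_axis()))
  set.seed(23)
  X3 <- array(rnorm(40 * 3 * m$slice_len), c(40, 3, m$slice_len))
  never <- predict(m, X3, type = "selective", threshold = 0)
  expect_true(all(never$label != "REJECT"))
  always <- predict(m, X3, type = "selective", threshold = 1)
  expect_true(all(always$label[always$confidence < 1] == "REJECT"))
  rates <- vapply(seq(0, 1, by = 0.1), function(th)
    mean(predict(m, X3, type = "selective", threshold = th)$label == "REJECT"),
    numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_error(predict(m, X3, type = "selective", threshold = 2), "threshold")
})

test_that("training is reproducible, improves the loss and never augments validation", {
  pp <- tiny_clean_set(seed = 30, n_cells = 5)
  cfg <- net_config(epochs = 6, seed = 9, augmentation = "both",
                    batch_size = 16)
  m <- build_model(cfg, length(pp$shifts))
  cv <- cv_config(k = 2, seed = 2)
  r1 <- cnn_train(m, pp, cv = cv, refit = FALSE)
  r2 <- cnn_train(m, pp, cv = cv, refit = FALSE)
  expect_identical(r1$fold_metrics, r2$fold_metrics)
  expect_true(all(!r1$fold_metrics$val_augmented))
  expect_equal(r1$fold_metrics$n_val, rep(25, 2), tolerance = 1)
  h <- r1$history[r1$history$fold == 1, ]
  expect_true(all(is.finite(h$train_loss)))
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
})

test_that("TPE returns in-bounds configurations with a non-decreasing best", {
  space <- list(lr = list(type = "loguniform", low = 1e-4, high = 0.05),
                x = list(type = "uniform", low = -2, high = 2),
                mode = list(type = "categorical", values = c("a", "b")))
  obj <- function(p)
    -(log10(p$lr) + 2.3)^2 - (p$x - 0.5)^2 + (p$mode == "b")
  one <- hpo_tpe(obj, space, budget = 1, seed = 3)
  expect_equal(nrow(one$history), 1)
  expect_true(one$best$lr >= 1e-4 && one$best$lr <= 0.05)
  r5 <- hpo_tpe(obj, space, budget = 5, seed = 3)
  r15 <- hpo_tpe(obj, space, budget = 15, seed = 3)
  expect_gte(r15$best_value, r5$best_value)
  expect_true(all(r15$history$lr >= 1e-4 & r15$history$lr <= 0.05))
  expect_true(all(r15$history$x >= -2 & r15$history$x <= 2))
  expect_error(hpo_tpe(obj, space, budget = 0), "budget")
})

test_that("the ablation grid covers all 16 cells with consistent F1", {
  cfg <- sim_config(n_cells_per_class = 5, spectra_per_cell = 5, seed = 33)
  pp <- preprocess_spectra(generate_dataset(cfg))
  tab <- ablation_grid(pp, epochs = 2, k = 2, seed = 4)
  expect_equal(nrow(tab), 16)
  expect_equal(unique(tab$n_layers), c(25, 56))
  expect_equal(sort(unique(tab$reject)), c(0.2, 0.8))
  expect_setequal(unique(tab$augmentation),
                  c("none", "frequency", "value", "both"))
  ok <- !is.na(tab$f1)
  expect_equal(tab$f1[ok],
               2 * tab$precision[ok] * tab$recall[ok] /
                 (tab$precision[ok] + tab$recall[ok]),
               tolerance = 5e-4)
})
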