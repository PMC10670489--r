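#' CNN-LSTM network configuration
#'
#' Two depth variants are available (25 and 56 named layers). Each spectrum
#' is cut into `k_s` equal slices; a shared 1-D convolutional stack with 64,
#' 128 and 256 filters (the deep variant repeats filter sizes) extracts
#' per-slice features, an LSTM integrates the slice sequence, and a softmax
#' head classifies. A parallel selective branch produces a confidence score:
#' predictions below `reject_threshold` are rejected. Two dropout sites
#' exist: the tuned `dropout` on the flattened slice features and the fixed
#' `head_dropout` (0.5) after the LSTM.
#'
#' @param n_layers 25 or 56.
#' @param learning_rate Adam step size, in `[0.0001, 0.05]`.
#' @param dropout tuned dropout rate, in `[0.1, 0.25]`.
#' @param k_s number of non-overlapping slices per spectrum (default 3).
#' @param kernel_width convolution kernel length (default 4).
#' @param lstm_units LSTM state size (default 100).
#' @param head_dropout dropout after the LSTM (default 0.5).
#' @param reject_threshold confidence threshold of the reject option
#'   (typically 0.2 or 0.8), or `NULL` to disable rejection at prediction
#'   time.
#' @param selective train the selective (confidence) branch (default TRUE).
#' @param augmentation `"none"`, `"frequency"`, `"value"` or `"both"`.
#' @param augment_pct augmentation magnitude, percent (default 10).
#' @param lambda coverage-penalty weight of the selective loss (default 32).
#' @param target_coverage selective-loss target coverage (default 0.9).
#' @param epochs maximum training epochs.
#' @param batch_size mini-batch size (default 32).
#' @param patience early-stopping patience on validation loss.
#' @param seed integer seed for weight initialization and training.
#' @return list of class `net_config`.
#' @export
net_config <- function(n_layers = 25, learning_rate = 0.001, dropout = 0.15,
                       k_s = 3, kernel_width = 4, lstm_units = 100,
                       head_dropout = 0.5, reject_threshold = NULL,
                       selective = TRUE,
                       augmentation = c("none", "frequency", "value", "both"),
                       augment_pct = 10, lambda = 32, target_coverage = 0.9,
                       epochs = 30, batch_size = 32, patience = 10,
                       seed = 1) {
  augmentation <- match.arg(augmentation)
  if (!n_layers %in% c(25, 56)) stop("`n_layers` must be 25 or 56")
  if (learning_rate < 1e-4 || learning_rate > 0.05)
    stop("`learning_rate` must lie in [0.0001, 0.05]")
  if (dropout < 0.1 || dropout > 0.25)
    stop("`dropout` must lie in [0.1, 0.25]")
  if (!is.null(reject_threshold) &&
      (reject_threshold < 0 || reject_threshold > 1))
    stop("`reject_threshold` must lie in [0, 1]")
  stopifnot(k_s >= 1, kernel_width >= 2, lstm_units >= 1, epochs >= 1,
            batch_size >= 1)
  structure(list(n_layers = n_layers, learning_rate = learning_rate,
                 dropout = dropout, k_s = as.integer(k_s),
                 kernel_width = as.integer(kernel_width),
                 lstm_units = as.integer(lstm_units),
                 head_dropout = head_dropout,
                 reject_threshold = reject_threshold,
                 selective = isTRUE(selective), augmentation = augmentation,
                 augment_pct = augment_pct, lambda = lambda,
                 target_coverage = target_coverage,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = seed),
            class = "net_config")
}

#' Cut a spectrum into equal non-overlapping slices
#'
#' Produces `k_s` contiguous equal-length slices; when the length is not a
#' multiple of `k_s`, trailing points are dropped, so concatenating the
#' slices reproduces the first `k_s * floor(n / k_s)` intensities.
#'
#' @param s a [raman_spectrum()] or numeric vector.
#' @param k_s number of slices (default 3).
#' @return object of class `windowed_spectrum`: list with `slices` (list of
#'   equal-length numeric vectors) and `source_id`.
#' @export
window_spectrum <- function(s, k_s = 3) {
  if (k_s < 1) stop("`k_s` must be >= 1")
  y <- if (inherits(s, "raman_spectrum")) s$intensities else as.numeric(s)
  if (length(y) < k_s) stop("spectrum shorter than `k_s`")
  L <- length(y) %/% k_s
  slices <- lapply(seq_len(k_s), function(j) y[((j - 1) * L + 1):(j * L)])
  structure(list(slices = slices,
                 source_id = if (inherits(s, "raman_spectrum"))
                   s$cell_id else NA_character_),
            class = "windowed_spectrum")
}

# Whole-set windowing into an array [n, k_s, L].
window_set <- function(set, k_s = 3) {
  n <- n_spectra(set)
  L <- length(set$shifts) %/% k_s
  X <- array(0, c(n, k_s, L))
  for (j in seq_len(k_s))
    X[, j, ] <- set$intensities[, ((j - 1) * L + 1):(j * L), drop = FALSE]
  X
}

#' Intensity (value) augmentation of a window
#'
#' Multiplies the whole window by a factor drawn uniformly from
#' `[1 - pct/100, 1 + pct/100]`, emulating small acquisition-to-acquisition
#' intensity variation. Zero-mean: averaging many augmented copies recovers
#' the input.
#'
#' @param slice numeric vector.
#' @param pct maximum perturbation, percent (default 10).
#' @return perturbed numeric vector of the same length.
#' @export
augment_value <- function(slice, pct = 10) {
  stopifnot(pct >= 0)
  slice * stats::runif(1, 1 - pct / 100, 1 + pct / 100)
}

# Resample a slice after translating its axis by `d` grid points
# (fractional allowed); boundaries are padded with the edge value.
shift_slice <- function(slice, d) {
  L <- length(slice)
  stats::approx(seq_len(L), slice, xout = seq_len(L) - d, rule = 2)$y
}

#' Frequency (axis-shift) augmentation of a window
#'
#' Translates the window's axis by a random amount of magnitude at most
#' `pct`% of the window length and resamples by linear interpolation (edges
#' padded with the boundary value), emulating small peak-position shifts
#' from instrument recalibration.
#'
#' @param slice numeric vector.
#' @param pct maximum shift, percent of the window length (default 10).
#' @return shifted numeric vector of the same length.
#' @export
augment_frequency <- function(slice, pct = 10) {
  stopifnot(pct >= 0)
  if (pct == 0) return(slice)
  d <- stats::runif(1, -1, 1) * pct / 100 * length(slice)
  shift_slice(slice, d)
}

# Augment a whole window array [n, ks, L] according to the config mode.
augment_windows <- function(X3, mode, pct) {
  if (mode == "none" || pct == 0) return(X3)
  n <- dim(X3)[1]; ks <- dim(X3)[2]; L <- dim(X3)[3]
  if (mode %in% c("value", "both")) {
    fac <- stats::runif(n * ks, 1 - pct / 100, 1 + pct / 100)
    X3 <- X3 * array(fac, c(n, ks, L))
  }
  if (mode %in% c("frequency", "both")) {
    for (i in seq_len(n)) for (j in seq_len(ks)) {
      d <- stats::runif(1, -1, 1) * pct / 100 * L
      X3[i, j, ] <- shift_slice(X3[i, j, ], d)
    }
  }
  X3
}

# Named-layer manifest of an architecture; the row count defines the
# advertised layer count (time-distributed per-slice copies are counted).
model_manifest <- function(cfg) {
  arch <- cnn_arch(cfg)
  rows <- list(data.frame(layer = "input", copies = 1))
  for (i in seq_along(arch$conv)) {
    cv <- arch$conv[[i]]
    rows <- c(rows, list(
      data.frame(layer = sprintf("td_conv1d_%d (%d filters, k=%d, stride=%d)",
                                 i, cv$f, cv$k, cv$s), copies = cfg$k_s),
      data.frame(layer = sprintf("td_relu_%d", i), copies = cfg$k_s)))
  }
  rows <- c(rows, list(
    data.frame(layer = sprintf("dropout_features (p=%.2f)", cfg$dropout),
               copies = 1),
    data.frame(layer = "flatten", copies = 1),
    data.frame(layer = sprintf("lstm (%d units)", cfg$lstm_units), copies = 1),
    data.frame(layer = sprintf("dropout_head (p=%.2f)", cfg$head_dropout),
               copies = 1)))
  if (arch$head_hidden > 0)
    rows <- c(rows, list(
      data.frame(layer = sprintf("dense (%d units)", arch$head_hidden),
                 copies = 1),
      data.frame(layer = "relu_head", copies = 1)))
  rows <- c(rows, list(data.frame(layer = "dense (2 units)", copies = 1),
                       data.frame(layer = "softmax", copies = 1)))
  if (cfg$n_layers == 56)
    rows <- c(rows, list(
      data.frame(layer = "selective_dense (32 units)", copies = 1),
      data.frame(layer = "selective_relu", copies = 1),
      data.frame(layer = "selective_dense (1 unit)", copies = 1),
      data.frame(layer = "selective_sigmoid", copies = 1),
      data.frame(layer = "selective_gate", copies = 1)))
  out <- do.call(rbind, rows)
  out <- out[rep(seq_len(nrow(out)), out$copies), "layer", drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build an (untrained) CNN-LSTM classifier
#'
#' Initializes the network weights for spectra of a given length. The build
#' is deterministic given `cfg$seed`; the named-layer manifest (including
#' per-slice copies of the time-distributed layers) has exactly
#' `cfg$n_layers` rows.
#'
#' @param cfg a [net_config()].
#' @param n_points number of points per (preprocessed) spectrum.
#' @return object of class `raman_cnn` with elements `cfg`, `params`,
#'   `manifest`, `n_params`, `slice_len`, `classes`.
#' @export
build_model <- function(cfg = net_config(), n_points) {
  slice_len <- n_points %/% cfg$k_s
  params <- with_seed(cfg$seed, nn_init(cfg, slice_len))
  manifest <- model_manifest(cfg)
  structure(list(cfg = cfg, params = params, manifest = manifest,
                 n_params = sum(vapply(params, length, integer(1))),
                 slice_len = slice_len, n_points = n_points,
                 classes = RAMAN_CLASSES, trained = FALSE,
                 pp_config = NULL),
            class = "raman_cnn")
}

#' @export
print.raman_cnn <- function(x, ...) {
  cat(sprintf("<raman_cnn> %d-layer CNN-LSTM, %s parameters, %s\n",
              x$cfg$n_layers, format(x$n_params, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  cat(sprintf("  k_s = %d slices of %d points; augmentation = %s; reject = %s\n",
              x$cfg$k_s, x$slice_len, x$cfg$augmentation,
              if (is.null(x$cfg$reject_threshold)) "off"
              else format(x$cfg$reject_threshold)))
  invisible(x)
}

#' @export
summary.raman_cnn <- function(object, ...) {
  print(object)
  print(object$manifest)
  invisible(object)
}

#' Train the CNN-LSTM with k-fold cross-validation
#'
#' Splits the spectra into `cv$k` stratified folds; for each fold the network
#' is trained on the remaining folds (with augmentation applied to the
#' training windows only — validation windows are never augmented) and
#' evaluated on the held-out fold. Per-fold precision, recall and F1 (Tumor
#' positive) and the loss curves are recorded. Optionally refits on the full
#' data for subsequent blind prediction.
#'
#' @param model a [build_model()] result.
#' @param set a preprocessed, labeled [raman_set()].
#' @param cv a [cv_config()].
#' @param refit refit on all spectra after cross-validation (default TRUE).
#' @param verbose print per-epoch losses.
#' @return the model with `fold_metrics` (data frame), `history` (per-fold
#'   loss curves), `cv_f1` (mean fold F1), and trained parameters when
#'   `refit = TRUE`.
#' @export
cnn_train <- function(model, set, cv = cv_config(k = 5, seed = model$cfg$seed),
                      refit = TRUE, verbose = FALSE) {
  stopifnot(inherits(model, "raman_cnn"), inherits(set, "raman_set"))
  cfg <- model$cfg
  labs <- set_labels(set)
  if (!all(labs %in% model$classes))
    stop("all spectra must be labeled Tumor or Non-Tumor")
  X3 <- window_set(set, cfg$k_s)
  y <- as.integer(labs == model$classes[2]) + 1L
  folds <- cv_folds(labs, cv, set$meta$cell_id)
  aug_fun <- if (cfg$augmentation == "none") NULL else
    function(X) augment_windows(X, cfg$augmentation, cfg$augment_pct)
  fm <- vector("list", cv$k); histories <- vector("list", cv$k)
  with_seed(cfg$seed, {
    for (f in seq_len(cv$k)) {
      tr <- folds != f
      fit <- nn_fit(with_seed(cfg$seed, nn_init(cfg, model$slice_len)),
                    X3[tr, , , drop = FALSE], y[tr], cfg,
                    Xval = X3[!tr, , , drop = FALSE], yval = y[!tr],
                    aug_fun = aug_fun, verbose = verbose)
      pred <- nn_pass(fit$params, X3[!tr, , , drop = FALSE], NULL, cfg)
      lab_pred <- model$classes[max.col(pred$probs)]
      mt <- compute_metrics(labs[!tr], lab_pred, positive = model$classes[2])
      fm[[f]] <- data.frame(fold = f, precision = mt$precision,
                            recall = mt$sensitivity, f1 = mt$f1,
                            n_val = sum(!tr), val_augmented = FALSE)
      histories[[f]] <- cbind(fold = f, fit$history)
    }
    if (refit) {
      fit <- nn_fit(model$params, X3, y, cfg, aug_fun = aug_fun,
                    verbose = verbose)
      model$params <- fit$params
      model$trained <- TRUE
    }
  })
  model$fold_metrics <- do.call(rbind, fm)
  model$history <- do.call(rbind, histories)
  model$cv_f1 <- mean(model$fold_metrics$f1)
  model$pp_config <- attr(set, "pp_config")
  model
}

#' @export
plot.raman_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history; run cnn_train()")
  h <- x$history
  graphics::plot(h$epoch, h$train_loss, type = "n",
                 xlab = "Epoch", ylab = "Loss", ...)
  for (f in unique(h$fold))
    graphics::lines(h$epoch[h$fold == f], h$train_loss[h$fold == f],
                    col = "grey50")
  graphics::legend("topright", "per-fold training loss", lty = 1,
                   col = "grey50", bty = "n")
  invisible(x)
}

#' @export
predict.raman_cnn <- function(object, newdata,
                              type = c("label", "prob", "selective"),
                              threshold = object$cfg$reject_threshold, ...) {
  type <- match.arg(type)
  X3 <- if (inherits(newdata, "raman_set"))
    window_set(newdata, object$cfg$k_s)
  else newdata
  out <- nn_pass(object$params, X3, NULL, object$cfg)
  if (type == "prob") return(out$probs)
  lab <- object$classes[max.col(out$probs)]
  if (type == "label") return(lab)
  if (is.null(out$conf)) stop("model has no selective branch")
  if (is.null(threshold)) threshold <- 0
  if (threshold < 0 || threshold > 1) stop("`threshold` must lie in [0, 1]")
  data.frame(label = ifelse(out$conf < threshold, "REJECT", lab),
             confidence = out$conf, threshold_used = threshold,
             stringsAsFactors = FALSE)
}

#' Selective (reject-option) prediction
#'
#' Predicts class labels but abstains (`"REJECT"`) whenever the selective
#' branch's confidence falls below `threshold`.
#'
#' @param model a trained [build_model()]/[cnn_train()] model with a
#'   selective branch.
#' @param newdata a preprocessed [raman_set()] or window array.
#' @param threshold confidence threshold in `[0, 1]`.
#' @return data frame with columns `label` (class or `"REJECT"`),
#'   `confidence`, `threshold_used`.
#' @export
selective_predict <- function(model, newdata,
                              threshold = model$cfg$reject_threshold) {
  predict(model, newdata, type = "selective", threshold = threshold)
}

#' Default TPE search space for the CNN-LSTM
#'
#' Bounds follow the tuned surface of the network: depth variant, learning
#' rate (log-uniform on `[0.0001, 0.05]`), dropout (`[0.1, 0.25]`), reject
#' threshold (0.2 or 0.8) and augmentation mode.
#'
#' @return named list of parameter descriptors for [hpo_tpe()].
#' @export
default_cnn_space <- function() {
  list(n_layers = list(type = "categorical", values = c(25, 56)),
       learning_rate = list(type = "loguniform", low = 1e-4, high = 0.05),
       dropout = list(type = "uniform", low = 0.1, high = 0.25),
       reject_threshold = list(type = "categorical", values = c(0.2, 0.8)),
       augmentation = list(type = "categorical",
                           values = c("none", "frequency", "value", "both")))
}

tpe_sample_prior <- function(space) {
  lapply(space, function(sp) switch(sp$type,
    uniform = stats::runif(1, sp$low, sp$high),
    loguniform = exp(stats::runif(1, log(sp$low), log(sp$high))),
    categorical = sp$values[[sample.int(length(sp$values), 1)]],
    stop("unknown parameter type")))
}

# One TPE proposal: split history at the gamma-quantile into good/bad,
# model each side with a Parzen (kernel-density / smoothed-count) estimator,
# and pick the candidate maximizing the good/bad density ratio.
tpe_propose <- function(space, hist_params, hist_value, gamma, n_candidates) {
  n <- length(hist_value)
  n_good <- max(1L, ceiling(gamma * n))
  ord <- order(hist_value, decreasing = TRUE)
  good <- ord[seq_len(n_good)]; bad <- ord[-seq_len(n_good)]
  if (length(bad) == 0) bad <- ord
  prop <- list()
  for (nm in names(space)) {
    sp <- space[[nm]]
    gv <- vapply(hist_params[good], function(p) p[[nm]], hist_params[[1]][[nm]])
    bv <- vapply(hist_params[bad], function(p) p[[nm]], hist_params[[1]][[nm]])
    if (sp$type == "categorical") {
      k <- length(sp$values)
      lg <- (tabulate(match(gv, sp$values), k) + 1) / (length(gv) + k)
      lb <- (tabulate(match(bv, sp$values), k) + 1) / (length(bv) + k)
      prop[[nm]] <- sp$values[[which.max(lg / lb)]]
    } else {
      lo <- if (sp$type == "loguniform") log(sp$low) else sp$low
      hi <- if (sp$type == "loguniform") log(sp$high) else sp$high
      tg <- if (sp$type == "loguniform") log(as.numeric(gv)) else as.numeric(gv)
      tb <- if (sp$type == "loguniform") log(as.numeric(bv)) else as.numeric(bv)
      bw <- (hi - lo) / sqrt(length(tg) + 2)
      cand <- stats::rnorm(n_candidates, sample(tg, n_candidates, TRUE), bw)
      cand <- pmin(pmax(cand, lo), hi)
      dens <- function(x, centers) rowMeans(outer(x, centers,
        function(a, b) stats::dnorm(a, b, bw)) + 1e-12)
      score <- dens(cand, tg) / dens(cand, tb)
      best <- cand[which.max(score)]
      val <- if (sp$type == "loguniform") exp(best) else best
      prop[[nm]] <- min(max(val, sp$low), sp$high)  # guard rounding at bounds
    }
  }
  prop
}

#' Tree-structured Parzen estimator hyper-parameter optimization
#'
#' Sequential model-based maximization of `objective` over a bounded space.
#' The first `n_startup` trials sample the prior; afterwards each trial
#' splits the history into good and bad configurations at the
#' `gamma`-quantile of the objective, fits Parzen estimators to both, and
#' proposes the candidate maximizing their density ratio.
#'
#' @param objective function taking a named list of parameter values and
#'   returning a scalar to maximize (e.g. mean CV F1).
#' @param space named list of parameter descriptors, each
#'   `list(type = "uniform"|"loguniform"|"categorical", ...)`; see
#'   [default_cnn_space()].
#' @param budget number of trials (>= 1).
#' @param seed integer seed.
#' @param gamma good/bad split quantile (default 0.25).
#' @param n_startup prior-sampled warm-up trials (default 5).
#' @param n_candidates candidates scored per numeric parameter (default 24).
#' @return list with `best` (parameter list), `best_value`, and `history`
#'   (data frame of all trials).
#' @export
hpo_tpe <- function(objective, space = default_cnn_space(), budget = 10,
                    seed = 1, gamma = 0.25, n_startup = 5,
                    n_candidates = 24) {
  if (budget < 1) stop("`budget` must be >= 1")
  with_seed(seed, {
    hist_params <- vector("list", budget)
    hist_value <- numeric(budget)
    for (i in seq_len(budget)) {
      prop <- if (i <= n_startup || i <= 2)
        tpe_sample_prior(space)
      else
        tpe_propose(space, hist_params[seq_len(i - 1)],
                    hist_value[seq_len(i - 1)], gamma, n_candidates)
      hist_params[[i]] <- prop
      hist_value[i] <- objective(prop)
    }
    best <- which.max(hist_value)
    hist_df <- do.call(rbind, lapply(seq_len(budget), function(i)
      cbind(data.frame(trial = i, value = hist_value[i]),
            as.data.frame(hist_params[[i]], stringsAsFactors = FALSE))))
    list(best = hist_params[[best]], best_value = hist_value[best],
         history = hist_df)
  })
}

#' Ablation grid over depth, reject threshold and augmentation
#'
#' Trains and cross-validates the CNN-LSTM for every combination of the two
#' depth variants (each with its reference learning rate and dropout:
#' 25 layers / lr 0.001 / dropout 0.15 and 56 layers / lr 0.01 / dropout
#' 0.2), two reject thresholds and four augmentation modes — a 16-row table
#' of precision, recall and F1.
#'
#' @param set a preprocessed, labeled [raman_set()].
#' @param n_layers depth variants (default `c(25, 56)`).
#' @param reject reject thresholds (default `c(0.2, 0.8)`).
#' @param augmentation augmentation modes (default all four).
#' @param epochs,k training epochs and CV folds per cell of the grid.
#' @param seed integer seed.
#' @return data frame with columns `n_layers`, `lr`, `dropout`, `reject`,
#'   `augmentation`, `precision`, `recall`, `f1`.
#' @export
ablation_grid <- function(set, n_layers = c(25, 56), reject = c(0.2, 0.8),
                          augmentation = c("none", "frequency", "value",
                                           "both"),
                          epochs = 30, k = 5, seed = 1) {
  ref <- list(`25` = list(lr = 0.001, dropout = 0.15),
              `56` = list(lr = 0.01, dropout = 0.2))
  rows <- list()
  for (nl in n_layers) for (rj in reject) for (au in augmentation) {
    cfg <- net_config(n_layers = nl, learning_rate = ref[[as.character(nl)]]$lr,
                      dropout = ref[[as.character(nl)]]$dropout,
                      reject_threshold = rj, augmentation = au,
                      epochs = epochs, seed = seed)
    model <- build_model(cfg, length(set$shifts))
    model <- cnn_train(model, set, cv = cv_config(k = k, seed = seed),
                       refit = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      n_layers = nl, lr = cfg$learning_rate, dropout = cfg$dropout,
      reject = rj, augmentation = au,
      precision = mean(model$fold_metrics$precision),
      recall = mean(model$fold_metrics$recall),
      f1 = f_score(mean(model$fold_metrics$precision),
                   mean(model$fold_metrics$recall)))
  }
  do.call(rbind, rows)
}
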