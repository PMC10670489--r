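# NIPALS PLS1: X (n x p, will be centered), y numeric response (centered).
# Returns weights W, loadings P, scores T, and the X-residual matrix.
nipals_pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(ncomp >= 1, ncomp < n)
  xc <- colMeans(X); yc <- mean(y)
  E <- sweep(X, 2, xc); f <- y - yc
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  TT <- matrix(0, n, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) stop("degenerate data: zero covariance with the response")
    w <- w / nw
    t_a <- drop(E %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(E, t_a)) / tt
    q[a] <- sum(f * t_a) / tt
    E <- E - tcrossprod(t_a, p_a)
    f <- f - q[a] * t_a
    W[, a] <- w; P[, a] <- p_a; TT[, a] <- t_a
  }
  # projection matrix for new samples: T_new = (X_new - center) %*% R
  R <- W %*% solve(crossprod(P, W))
  list(center = xc, W = W, P = P, R = R, scores = TT, q = q, residuals = E)
}

# Jackson-Mudholkar approximation of the (1 - alpha) Q-residual limit from
# the eigenvalues of the residual covariance.
q_limit_jm <- function(lambda, alpha = 0.05) {
  lambda <- lambda[lambda > max(lambda, 0) * 1e-12]
  if (length(lambda) == 0) return(0)
  th1 <- sum(lambda); th2 <- sum(lambda^2); th3 <- sum(lambda^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 < 1e-3) h0 <- 1e-3
  ca <- stats::qnorm(1 - alpha)
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 +
           th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}

#' Fit a PLS-based outlier screening model
#'
#' Fits a single-response PLS (PLS1-DA, class coded Non-Tumor = 0, Tumor = 1)
#' on preprocessed spectra and derives two per-spectrum statistics: the
#' Q-residual (squared norm of the part of a spectrum the latent-variable
#' model cannot reconstruct) and Hotelling's T-squared (Mahalanobis distance
#' inside the score space). Their 95% confidence limits come from the
#' Jackson-Mudholkar approximation (Q, using the residual covariance
#' eigenvalues) and the F-distribution with (A, N - A) degrees of freedom
#' (T-squared).
#'
#' @param set a preprocessed, labeled [raman_set()].
#' @param n_components number of PLS latent variables (default 5).
#' @param alpha significance level of the limits (default 0.05).
#' @return object of class `raman_outlier_model` with elements `n_components`,
#'   `scores`, `q_stats`, `t2_stats`, `q_limit`, `t2_limit`, plus the
#'   projection needed to score new spectra.
#' @export
fit_outlier_model <- function(set, n_components = 5, alpha = 0.05) {
  stopifnot(inherits(set, "raman_set"))
  labs <- set_labels(set)
  if (!all(labs %in% RAMAN_CLASSES))
    stop("all spectra must be labeled Tumor or Non-Tumor")
  X <- set$intensities
  if (n_components >= nrow(X))
    stop("`n_components` must be smaller than the number of spectra")
  y <- as.numeric(labs == "Tumor")
  fit <- nipals_pls1(X, y, n_components)
  q_stats <- rowSums(fit$residuals^2)
  score_sd <- apply(fit$scores, 2, stats::sd)
  t2_stats <- rowSums(sweep(fit$scores, 2, score_sd, "/")^2)
  n <- nrow(X); A <- n_components
  t2_limit <- A * (n - 1) / (n - A) * stats::qf(1 - alpha, A, n - A)
  sv <- svd(scale(fit$residuals, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  q_limit <- q_limit_jm(sv^2 / (n - 1), alpha)
  structure(list(n_components = A, center = fit$center, R = fit$R, P = fit$P,
                 score_sd = score_sd, scores = fit$scores, q_stats = q_stats,
                 t2_stats = t2_stats, q_limit = q_limit, t2_limit = t2_limit,
                 alpha = alpha, n_train = n),
            class = "raman_outlier_model")
}

#' @export
print.raman_outlier_model <- function(x, ...) {
  cat(sprintf(paste0("<raman_outlier_model> %d PLS components, N = %d\n",
                     "  Q limit (%.0f%%):  %.4g\n  T2 limit (%.0f%%): %.4g\n"),
              x$n_components, x$n_train, 100 * (1 - x$alpha), x$q_limit,
              100 * (1 - x$alpha), x$t2_limit))
  invisible(x)
}

# Q and T2 statistics of (possibly new) spectra under a fitted model.
outlier_stats <- function(model, X) {
  Xc <- sweep(X, 2, model$center)
  TT <- Xc %*% model$R
  E <- Xc - tcrossprod(TT, model$P)
  list(q = rowSums(E^2),
       t2 = rowSums(sweep(TT, 2, model$score_sd, "/")^2))
}

#' Flag outlying spectra
#'
#' Marks spectra whose Q-residual and/or T-squared exceed the fitted 95%
#' limits. Rule `"either"` (default) flags when either statistic exceeds its
#' limit; `"both"` requires both.
#'
#' @param set the [raman_set()] the model was fitted on (or a compatible one).
#' @param model a [fit_outlier_model()] result.
#' @param rule `"either"` or `"both"`.
#' @return `set` with `meta$outlier_flag` updated and a per-spectrum report
#'   attached as attribute `"qc_report"` (data frame with Q, T2 and flags).
#' @export
flag_outliers <- function(set, model, rule = c("either", "both")) {
  rule <- match.arg(rule)
  stopifnot(inherits(model, "raman_outlier_model"))
  st <- outlier_stats(model, set$intensities)
  q_ex <- st$q > model$q_limit
  t2_ex <- st$t2 > model$t2_limit
  flag <- if (rule == "either") q_ex | t2_ex else q_ex & t2_ex
  set$meta$outlier_flag <- flag
  attr(set, "qc_report") <- data.frame(
    spectrum_id = set$meta$spectrum_id, cell_id = set$meta$cell_id,
    label = set$meta$label, Q = st$q, T2 = st$t2,
    q_exceeded = q_ex, t2_exceeded = t2_ex, flagged = flag,
    stringsAsFactors = FALSE)
  set
}

#' Per-class outlier bookkeeping
#'
#' @param set a [raman_set()] with `outlier_flag` set (e.g. by
#'   [flag_outliers()]).
#' @return data frame with one row per class plus a `Total` row: spectra
#'   counts, flagged counts and retained counts.
#' @export
qc_summary <- function(set) {
  labs <- set_labels(set)
  classes <- unique(labs)
  rows <- lapply(classes, function(cl) {
    sel <- labs == cl
    data.frame(class = cl, n = sum(sel),
               flagged = sum(set$meta$outlier_flag[sel]),
               retained = sum(sel) - sum(set$meta$outlier_flag[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(class = "Total", n = sum(out$n),
                        flagged = sum(out$flagged),
                        retained = sum(out$retained)))
}

#' Drop flagged spectra
#' @param set a [raman_set()].
#' @return the subset with `outlier_flag == FALSE`.
#' @export
remove_outliers <- function(set) set[!set$meta$outlier_flag]

#' Write a QC report as TSV
#' @param set a set returned by [flag_outliers()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(set, path) {
  rep <- attr(set, "qc_report")
  if (is.null(rep)) stop("no qc_report attached; run flag_outliers() first")
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
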