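#' Blind prediction of the tumor fraction of a cell mixture
#'
#' Classifies every spectrum of an unlabeled set with a trained model and
#' estimates the tumor percentage from the spectrum-level votes:
#' `100 * n_predicted_tumor / n_non_rejected`. With a reject threshold (and a
#' model exposing a selective branch), rejected spectra are excluded from the
#' denominator and reported separately. The set must have been preprocessed
#' with the same configuration as the training data; a mismatch is an error.
#'
#' @param model a trained classifier (`raman_lda`, `raman_tuned_lda`,
#'   `raman_pca_lda` or `raman_cnn`).
#' @param set a preprocessed [raman_set()] (labels may be `"unknown"`).
#' @param reject_threshold optional confidence threshold (CNN-LSTM only).
#' @param model_name name recorded in the report.
#' @return object of class `mixture_report`: `model_name`, `n_spectra`,
#'   `n_rejected`, `n_predicted_tumor`, `percent_tumor` (`NA` if every
#'   spectrum was rejected), `nominal_percent` (if the set carries one),
#'   `votes` (per-spectrum labels).
#' @export
blind_predict <- function(model, set, reject_threshold = NULL,
                          model_name = class(model)[1]) {
  stopifnot(inherits(set, "raman_set"))
  mp <- model$pp_config
  sp <- attr(set, "pp_config")
  if (!is.null(mp) && !is.null(sp) && !identical(unclass(mp), unclass(sp)))
    stop("preprocessing configuration of `set` differs from the one used in training")
  if (!is.null(reject_threshold) && inherits(model, "raman_cnn")) {
    sel <- predict(model, set, type = "selective",
                   threshold = reject_threshold)
    votes <- sel$label
  } else {
    votes <- as.character(predict(model, set, type = "label"))
  }
  n <- length(votes)
  n_rej <- sum(votes == "REJECT")
  n_tum <- sum(votes == "Tumor")
  pct <- if (n - n_rej > 0) 100 * n_tum / (n - n_rej) else NA_real_
  structure(list(model_name = model_name, n_spectra = n, n_rejected = n_rej,
                 n_predicted_tumor = n_tum, percent_tumor = pct,
                 nominal_percent = nominal_percent(set), votes = votes),
            class = "mixture_report")
}

#' @export
print.mixture_report <- function(x, ...) {
  cat(sprintf("<mixture_report> %s: %d spectra", x$model_name, x$n_spectra))
  if (x$n_rejected > 0) cat(sprintf(" (%d rejected)", x$n_rejected))
  cat("\n")
  if (is.na(x$percent_tumor)) {
    cat("  tumor percentage undefined: all spectra rejected\n")
  } else {
    cat(sprintf("  predicted tumor: %.2f%%", x$percent_tumor))
    if (!is.na(x$nominal_percent))
      cat(sprintf("  (nominal %.2f%%)", x$nominal_percent))
    cat("\n")
  }
  invisible(x)
}

#' Tabulate mixture reports across models and blind sets
#'
#' @param reports a list of lists of [blind_predict()] reports: one element
#'   per model, each a list with one report per blind set (set order is
#'   preserved in the columns). A single flat list is treated as one model.
#' @param set_names optional column names.
#' @return object of class `mixture_comparison`: a models x sets data frame
#'   of tumor percentages, printed as a human-readable table.
#' @export
compare_models <- function(reports, set_names = NULL) {
  if (length(reports) == 0) stop("at least one report is required")
  if (inherits(reports[[1]], "mixture_report")) reports <- list(reports)
  tab <- do.call(rbind, lapply(reports, function(rr)
    vapply(rr, function(r) r$percent_tumor, numeric(1))))
  rownames(tab) <- vapply(reports, function(rr) rr[[1]]$model_name,
                          character(1))
  if (is.null(set_names)) {
    nominal <- vapply(reports[[1]], function(r) r$nominal_percent, numeric(1))
    set_names <- if (all(!is.na(nominal)))
      sprintf("nominal_%.0f", nominal) else sprintf("set_%d", seq_len(ncol(tab)))
  }
  colnames(tab) <- set_names
  out <- as.data.frame(tab)
  class(out) <- c("mixture_comparison", "data.frame")
  out
}

#' @export
print.mixture_comparison <- function(x, ...) {
  cat("Predicted tumor percentage per model and blind set:\n")
  print(round(as.data.frame(x), 2))
  invisible(x)
}

#' Write a mixture comparison as TSV
#' @param x a [compare_models()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  utils::write.table(cbind(model = rownames(x), as.data.frame(x)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
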