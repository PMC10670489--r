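#' @keywords internal
"_PACKAGE"

RAMAN_CLASSES <- c("Non-Tumor", "Tumor")

#' A single Raman spectrum
#'
#' Light-weight container for one Raman acquisition: a strictly increasing
#' Raman-shift grid (cm^-1), the matching intensities (a.u.), and provenance
#' metadata (cell of origin, class label, processing stage, outlier flag).
#'
#' @param shifts numeric vector of Raman shifts in cm^-1, strictly increasing.
#' @param intensities numeric vector of the same length as `shifts`.
#' @param cell_id identifier of the cell the spectrum was acquired from.
#' @param label class label: `"Tumor"`, `"Non-Tumor"` or `"unknown"`.
#' @param stage processing stage, `"raw"` or `"preprocessed"`.
#' @param outlier_flag logical, whether QC flagged the spectrum.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(shifts, intensities, cell_id = NA_character_,
                           label = "unknown", stage = "raw",
                           outlier_flag = FALSE) {
  shifts <- as.numeric(shifts)
  intensities <- as.numeric(intensities)
  if (length(shifts) != length(intensities))
    stop("`shifts` and `intensities` must have the same length")
  if (length(shifts) > 1L && any(diff(shifts) <= 0))
    stop("`shifts` must be strictly increasing")
  label <- match.arg(label, c(RAMAN_CLASSES, "unknown"))
  stage <- match.arg(stage, c("raw", "preprocessed"))
  structure(
    list(shifts = shifts, intensities = intensities,
         cell_id = as.character(cell_id), label = label, stage = stage,
         outlier_flag = isTRUE(outlier_flag)),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.1f-%.1f cm-1, cell %s, %s (%s)\n",
              length(x$shifts), min(x$shifts), max(x$shifts),
              x$cell_id, x$label, x$stage))
  invisible(x)
}

#' A set of Raman spectra on a common shift grid
#'
#' Spectra are stored row-wise in a numeric matrix; per-spectrum metadata
#' (cell id, class label, stage, QC flags) live in a companion data frame.
#' This is the container every pipeline stage consumes and returns.
#'
#' @param shifts common Raman-shift grid (cm^-1), strictly increasing.
#' @param intensities numeric matrix, one row per spectrum,
#'   `ncol == length(shifts)`.
#' @param meta data frame with one row per spectrum. Recognised columns:
#'   `spectrum_id`, `cell_id`, `label`, `stage`, `outlier_flag`,
#'   `outlier_truth` (simulator ground truth, `NA` for real data). Missing
#'   columns are filled with defaults.
#' @return An object of class `raman_set`.
#' @export
raman_set <- function(shifts, intensities, meta = NULL) {
  shifts <- as.numeric(shifts)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) > 0 && ncol(intensities) != length(shifts))
    stop("`intensities` must have one column per shift")
  if (length(shifts) > 1L && any(diff(shifts) <= 0))
    stop("`shifts` must be strictly increasing")
  n <- nrow(intensities)
  if (is.null(meta)) meta <- data.frame(row.names = seq_len(n))[seq_len(n), , drop = FALSE]
  meta <- as.data.frame(meta)
  if (n > 0 && nrow(meta) != n) stop("`meta` must have one row per spectrum")
  defaults <- list(spectrum_id = sprintf("s%04d", seq_len(n)),
                   cell_id = NA_character_, label = "unknown",
                   stage = "raw", outlier_flag = FALSE, outlier_truth = NA)
  for (nm in names(defaults))
    if (is.null(meta[[nm]])) meta[[nm]] <- if (n > 0) defaults[[nm]] else defaults[[nm]][0]
  rownames(meta) <- NULL
  structure(list(shifts = shifts, intensities = intensities, meta = meta),
            class = "raman_set")
}

#' Number of spectra in a set
#' @param set a [raman_set()].
#' @return integer count.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' @export
print.raman_set <- function(x, ...) {
  n <- n_spectra(x)
  cat(sprintf("<raman_set> %d spectra x %d points (%.1f-%.1f cm-1)\n",
              n, length(x$shifts),
              if (length(x$shifts)) min(x$shifts) else NA,
              if (length(x$shifts)) max(x$shifts) else NA))
  if (n > 0) {
    tab <- table(x$meta$label)
    cat("  labels: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n  stage:  ", paste(unique(x$meta$stage), collapse = ", "),
        sprintf("  (flagged outliers: %d)\n", sum(x$meta$outlier_flag)))
  }
  invisible(x)
}

#' @export
`[.raman_set` <- function(x, i, ...) {
  out <- raman_set(x$shifts, x$intensities[i, , drop = FALSE],
                   x$meta[i, , drop = FALSE])
  attributes(out)[setdiff(names(attributes(x)), c("names", "class"))] <-
    attributes(x)[setdiff(names(attributes(x)), c("names", "class"))]
  out
}

#' @export
as.matrix.raman_set <- function(x, ...) x$intensities

#' Extract one spectrum from a set
#' @param set a [raman_set()].
#' @param i row index.
#' @return a [raman_spectrum()].
#' @export
get_spectrum <- function(set, i) {
  stopifnot(i >= 1, i <= n_spectra(set))
  m <- set$meta[i, ]
  raman_spectrum(set$shifts, set$intensities[i, ], cell_id = m$cell_id,
                 label = m$label, stage = m$stage,
                 outlier_flag = m$outlier_flag)
}

#' Combine a single spectrum into a one-row set
#' @param s a [raman_spectrum()].
#' @return a [raman_set()] with one row.
#' @export
as_raman_set <- function(s) {
  stopifnot(inherits(s, "raman_spectrum"))
  raman_set(s$shifts, matrix(s$intensities, nrow = 1),
            data.frame(spectrum_id = "s0001", cell_id = s$cell_id,
                       label = s$label, stage = s$stage,
                       outlier_flag = s$outlier_flag, outlier_truth = NA))
}

#' Class labels of a set
#' @param set a [raman_set()].
#' @return character vector of labels.
#' @export
set_labels <- function(set) as.character(set$meta$label)

#' @export
plot.raman_set <- function(x, ..., col = c("black", "red3")) {
  if (n_spectra(x) == 0) stop("empty set")
  labs <- set_labels(x)
  classes <- intersect(RAMAN_CLASSES, unique(labs))
  if (length(classes) == 0) classes <- unique(labs)
  means <- lapply(classes, function(cl)
    colMeans(x$intensities[labs == cl, , drop = FALSE]))
  ylim <- range(unlist(means))
  graphics::plot(x$shifts, means[[1]], type = "l", col = col[1], ylim = ylim,
                 xlab = expression("Raman shift (cm"^-1 * ")"),
                 ylab = "Intensity (a.u.)", ...)
  if (length(means) > 1)
    graphics::lines(x$shifts, means[[2]], col = col[2])
  graphics::legend("topleft", legend = classes, col = col[seq_along(classes)],
                   lty = 1, bty = "n")
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}
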