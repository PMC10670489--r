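#' Write a spectrum set as per-spectrum CSV files plus a manifest
#'
#' Each spectrum becomes one two-column CSV (`shift_cm-1,intensity`); a
#' `manifest.tsv` lists `spectrum_path`, `cell_id`, `label`, `stage` and
#' `is_outlier_truth`.
#'
#' @param set a [raman_set()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_spectra <- function(set, dir) {
  stopifnot(inherits(set, "raman_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(set$meta$spectrum_id, ".csv"))
  for (i in seq_len(n_spectra(set))) {
    df <- data.frame(set$shifts, set$intensities[i, ])
    names(df) <- c("shift_cm-1", "intensity")
    utils::write.csv(df, paths[i], row.names = FALSE, quote = FALSE)
  }
  manifest <- data.frame(spectrum_path = basename(paths),
                         cell_id = set$meta$cell_id,
                         label = set$meta$label, stage = set$meta$stage,
                         is_outlier_truth = set$meta$outlier_truth)
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}

#' Read a spectrum set written by [write_spectra()]
#'
#' @param dir directory containing the per-spectrum CSVs and `manifest.tsv`.
#' @return a [raman_set()].
#' @export
read_spectra <- function(dir) {
  mpath <- file.path(dir, "manifest.tsv")
  if (!file.exists(mpath)) stop("no manifest.tsv in `dir`")
  manifest <- utils::read.delim(mpath, stringsAsFactors = FALSE)
  first <- utils::read.csv(file.path(dir, manifest$spectrum_path[1]),
                           check.names = FALSE)
  shifts <- first[[1]]
  y <- matrix(0, nrow(manifest), length(shifts))
  y[1, ] <- first[[2]]
  for (i in seq_len(nrow(manifest))[-1]) {
    df <- utils::read.csv(file.path(dir, manifest$spectrum_path[i]),
                          check.names = FALSE)
    if (!isTRUE(all.equal(df[[1]], shifts)))
      stop("spectra in `dir` are not on a common grid")
    y[i, ] <- df[[2]]
  }
  raman_set(shifts, y,
            data.frame(spectrum_id = sub("\\.csv$", "",
                                         manifest$spectrum_path),
                       cell_id = manifest$cell_id, label = manifest$label,
                       stage = manifest$stage, outlier_flag = FALSE,
                       outlier_truth = manifest$is_outlier_truth))
}
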