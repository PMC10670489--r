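#' Default Raman band table for liver-cell simulation
#'
#' One row per characteristic band of fixed single cells in the fingerprint
#' region, with assignments to the major biomolecule classes. Class asymmetry
#' follows the tumor vs non-tumor difference spectrum of primary liver cells:
#' nucleic-acid bands at 782-785, 1094, 1335, 1370 and 1578 cm^-1 are elevated
#' in tumor cells (higher DNA content in cancer nuclei), while the Amide III
#' band near 1240 cm^-1 and the CH2/CH3 deformation band at 1438 cm^-1 are
#' higher in non-tumor cells.
#'
#' @param tumor_up multiplier applied to tumor-elevated bands (default 1.25).
#' @param tumor_down multiplier applied to tumor-depressed bands (default 0.8).
#' @return data frame of class `band_table` with columns `center`, `width`
#'   (FWHM, cm^-1), `base_amplitude` (a.u.), `tumor_multiplier`, `assignment`.
#' @export
default_band_table <- function(tumor_up = 1.25, tumor_down = 0.8) {
  stopifnot(tumor_up > 1, tumor_down > 0, tumor_down < 1)
  b <- data.frame(
    center = c(729, 757, 784, 826, 854, 850, 1004, 1031, 1064, 1094, 1177,
               1207, 1243, 1305, 1335, 1370, 1438, 1444, 1578, 1606, 1618,
               1656),
    width = c(12, 12, 14, 12, 12, 30, 10, 12, 16, 16, 14,
              14, 25, 18, 18, 14, 20, 20, 16, 12, 12, 30),
    base_amplitude = c(0.25, 0.3, 0.6, 0.2, 0.3, 0.15, 0.8, 0.35, 0.3, 0.45,
                       0.25, 0.25, 0.45, 0.4, 0.55, 0.3, 0.5, 0.9, 0.4, 0.3,
                       0.3, 1.0),
    assignment = c("A ring breathing", "Trp ring breathing",
                   "DNA backbone / pyrimidine ring breathing", "O-P-O stretch",
                   "Tyr ring breathing", "polysaccharide",
                   "Phe ring breathing", "Phe C-H bend", "skeletal C-C",
                   "sym PO2- stretch", "Tyr C-H bend", "Phe/Trp C-C6H5",
                   "Amide III", "CH2 twist", "A,G ring breathing / C-H def",
                   "DNA bases ring breathing", "CH2,CH3 def (non-tumor)",
                   "CH2,CH3 def", "A,G ring breathing", "Tyr/Phe C=C",
                   "Phe,Tyr,Trp C=C", "Amide I"),
    stringsAsFactors = FALSE)
  up <- c(784, 1094, 1335, 1370, 1578)     # nucleic-acid bands, tumor-elevated
  down <- c(1243, 1438)                    # Amide III + CH2/CH3, tumor-depressed
  b$tumor_multiplier <- 1
  b$tumor_multiplier[b$center %in% up] <- tumor_up
  b$tumor_multiplier[b$center %in% down] <- tumor_down
  class(b) <- c("band_table", "data.frame")
  b
}

# Pseudo-Voigt line shape, unit peak height, 50/50 Gaussian/Lorentzian mix.
pseudo_voigt <- function(x, center, fwhm, eta = 0.5) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  gauss <- exp(-(x - center)^2 / (2 * sigma^2))
  lorentz <- (fwhm / 2)^2 / ((x - center)^2 + (fwhm / 2)^2)
  eta * lorentz + (1 - eta) * gauss
}

#' Simulation configuration
#'
#' Defines the study conditions the simulator emulates: 40 cells per class
#' with 5 spectra per cell on a 600-1800 cm^-1 grid, cell-level amplitude
#' heterogeneity, a smooth cubic fluorescence baseline, additive Gaussian
#' noise and an optional fraction of corrupted spectra.
#'
#' @param n_cells_per_class cells per class (default 40).
#' @param spectra_per_cell acquisitions per cell (default 5).
#' @param axis Raman-shift grid (default `seq(600, 1800, by = 1)`).
#' @param noise_sd additive Gaussian noise sd, a.u. (peak heights are O(1)).
#' @param baseline_coeffs_range list of 4 ranges (length-2 numerics) for the
#'   cubic baseline coefficients in the normalized coordinate
#'   `u = (shift - 600)/1200`.
#' @param cell_effect_sd log-normal sd of the per-cell factor multiplying the
#'   class-informative band amplitudes.
#' @param outlier_fraction proportion of spectra corrupted (in `[0, 1)`).
#' @param seed integer seed or `NULL`.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells_per_class = 40, spectra_per_cell = 5,
                       axis = seq(600, 1800, by = 1), noise_sd = 0.02,
                       baseline_coeffs_range = list(c(0.5, 1.5), c(-0.5, 0.5),
                                                    c(-0.5, 0.5), c(-0.5, 0.5)),
                       cell_effect_sd = 0.1, outlier_fraction = 0,
                       seed = NULL) {
  stopifnot(n_cells_per_class >= 1, spectra_per_cell >= 1, noise_sd >= 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            length(axis) > 1, all(diff(axis) > 0),
            length(baseline_coeffs_range) == 4)
  structure(list(n_cells_per_class = as.integer(n_cells_per_class),
                 spectra_per_cell = as.integer(spectra_per_cell),
                 axis = as.numeric(axis), noise_sd = noise_sd,
                 baseline_coeffs_range = baseline_coeffs_range,
                 cell_effect_sd = cell_effect_sd,
                 outlier_fraction = outlier_fraction, seed = seed),
            class = "sim_config")
}

# Random cubic baseline evaluated on cfg$axis (u in [0,1]).
random_baseline <- function(cfg) {
  co <- vapply(cfg$baseline_coeffs_range,
               function(r) stats::runif(1, r[1], r[2]), numeric(1))
  u <- (cfg$axis - min(cfg$axis)) / diff(range(cfg$axis))
  drop(cbind(1, u, u^2, u^3) %*% co)
}

#' Simulate one Raman spectrum
#'
#' Sum of pseudo-Voigt bands (amplitudes scaled by the class multiplier and
#' the per-cell heterogeneity factor on class-informative bands), plus a
#' random cubic fluorescence baseline and additive Gaussian noise. Uses the
#' current RNG stream, so it is deterministic given the RNG state.
#'
#' @param label `"Tumor"` or `"Non-Tumor"`.
#' @param bands a [default_band_table()]-style data frame.
#' @param cfg a [sim_config()].
#' @param cell_effect per-cell multiplicative factor for informative bands.
#' @param cell_id identifier recorded in the result.
#' @return a [raman_spectrum()], stage `"raw"`.
#' @export
generate_spectrum <- function(label, bands = default_band_table(),
                              cfg = sim_config(), cell_effect = 1,
                              cell_id = NA_character_) {
  if (!label %in% RAMAN_CLASSES)
    stop("`label` must be \"Tumor\" or \"Non-Tumor\"")
  y <- clean_signal(label, bands, cfg, cell_effect) +
    random_baseline(cfg) +
    stats::rnorm(length(cfg$axis), sd = cfg$noise_sd)
  raman_spectrum(cfg$axis, y, cell_id = cell_id, label = label, stage = "raw")
}

# Band contribution only (no baseline/noise); shared by generator and tests.
clean_signal <- function(label, bands, cfg, cell_effect = 1) {
  mult <- if (label == "Tumor") bands$tumor_multiplier else rep(1, nrow(bands))
  amp <- bands$base_amplitude * mult
  informative <- bands$tumor_multiplier != 1
  amp[informative] <- amp[informative] * cell_effect
  y <- numeric(length(cfg$axis))
  for (i in seq_len(nrow(bands)))
    y <- y + amp[i] * pseudo_voigt(cfg$axis, bands$center[i], bands$width[i])
  y
}

# Corrupt a spectrum in place: a narrow cosmic-ray-like spike, or a broad
# fluorescence surge that an order-3 polynomial cannot absorb.
corrupt_spectrum <- function(y, axis, max_amp, mode = c("spike", "surge")) {
  mode <- match.arg(mode)
  if (mode == "spike") {
    pos <- stats::runif(1, min(axis) + 20, max(axis) - 20)
    a <- stats::runif(1, 10, 30) * max_amp
    y + a * pseudo_voigt(axis, pos, stats::runif(1, 2, 4), eta = 0)
  } else {
    pos <- stats::runif(1, 800, 1600)
    a <- stats::runif(1, 8, 12) * max_amp
    y + a * exp(-(axis - pos)^2 / (2 * (stats::runif(1, 60, 110))^2))
  }
}

#' Simulate a labeled two-class dataset
#'
#' Generates `n_cells_per_class` cells per class with `spectra_per_cell`
#' spectra each. A per-cell log-normal factor modulates the class-informative
#' band amplitudes (intra-sample heterogeneity); exactly
#' `round(outlier_fraction * N)` spectra are corrupted and marked in
#' `meta$outlier_truth` for QC validation.
#'
#' @param cfg a [sim_config()].
#' @param bands a band table, see [default_band_table()].
#' @return a [raman_set()], stage `"raw"`.
#' @export
generate_dataset <- function(cfg = sim_config(), bands = default_band_table()) {
  with_seed(cfg$seed, {
    per_class <- cfg$n_cells_per_class * cfg$spectra_per_cell
    n <- 2L * per_class
    y <- matrix(0, n, length(cfg$axis))
    cell_id <- character(n); label <- character(n)
    row <- 0L
    for (cl in RAMAN_CLASSES) {
      prefix <- if (cl == "Tumor") "T" else "N"
      for (ci in seq_len(cfg$n_cells_per_class)) {
        eff <- stats::rlnorm(1, 0, cfg$cell_effect_sd)
        for (si in seq_len(cfg$spectra_per_cell)) {
          row <- row + 1L
          s <- generate_spectrum(cl, bands, cfg, cell_effect = eff,
                                 cell_id = sprintf("%s%02d", prefix, ci))
          y[row, ] <- s$intensities
          cell_id[row] <- s$cell_id; label[row] <- cl
        }
      }
    }
    truth <- rep(FALSE, n)
    n_out <- round(cfg$outlier_fraction * n)
    if (n_out > 0) {
      idx <- sample.int(n, n_out)
      max_amp <- max(bands$base_amplitude)
      for (i in idx) {
        mode <- sample(c("spike", "surge"), 1)
        y[i, ] <- corrupt_spectrum(y[i, ], cfg$axis, max_amp, mode)
      }
      truth[idx] <- TRUE
    }
    raman_set(cfg$axis, y,
              data.frame(spectrum_id = sprintf("s%04d", seq_len(n)),
                         cell_id = cell_id, label = label, stage = "raw",
                         outlier_flag = FALSE, outlier_truth = truth))
  })
}

#' Simulate a blind cell mixture
#'
#' Generates spectra for `n_tumor_cells` tumor and `n_nontumor_cells`
#' non-tumor cells, hides the labels (all `"unknown"`) and records the ground
#' truth out-of-band for later scoring. The nominal tumor fraction is defined
#' at the cell level, `100 * n_tumor_cells / (n_tumor_cells + n_nontumor_cells)`.
#'
#' @param n_tumor_cells,n_nontumor_cells cell counts (not both zero).
#' @param cfg a [sim_config()]; `n_cells_per_class` is ignored here.
#' @param bands a band table.
#' @return a [raman_set()] with hidden labels; attributes `nominal_percent`
#'   (numeric) and `true_labels` (character, the hidden ground truth).
#' @export
generate_mixture <- function(n_tumor_cells, n_nontumor_cells,
                             cfg = sim_config(), bands = default_band_table()) {
  stopifnot(n_tumor_cells >= 0, n_nontumor_cells >= 0)
  if (n_tumor_cells + n_nontumor_cells == 0)
    stop("at least one cell is required")
  with_seed(cfg$seed, {
    counts <- c("Tumor" = n_tumor_cells, "Non-Tumor" = n_nontumor_cells)
    n <- sum(counts) * cfg$spectra_per_cell
    y <- matrix(0, n, length(cfg$axis))
    cell_id <- character(n); truth <- character(n)
    row <- 0L; cell_no <- 0L
    for (cl in names(counts)) {
      for (ci in seq_len(counts[[cl]])) {
        cell_no <- cell_no + 1L
        eff <- stats::rlnorm(1, 0, cfg$cell_effect_sd)
        for (si in seq_len(cfg$spectra_per_cell)) {
          row <- row + 1L
          s <- generate_spectrum(cl, bands, cfg, cell_effect = eff,
                                 cell_id = sprintf("M%02d", cell_no))
          y[row, ] <- s$intensities
          cell_id[row] <- s$cell_id; truth[row] <- cl
        }
      }
    }
    out <- raman_set(cfg$axis, y,
                     data.frame(spectrum_id = sprintf("s%04d", seq_len(n)),
                                cell_id = cell_id, label = "unknown",
                                stage = "raw", outlier_flag = FALSE,
                                outlier_truth = FALSE))
    attr(out, "nominal_percent") <-
      100 * n_tumor_cells / (n_tumor_cells + n_nontumor_cells)
    attr(out, "true_labels") <- truth
    out
  })
}

#' Nominal tumor percentage of a simulated mixture
#' @param set a [generate_mixture()] result.
#' @return numeric percentage, or `NA` if unknown.
#' @export
nominal_percent <- function(set) {
  p <- attr(set, "nominal_percent")
  if (is.null(p)) NA_real_ else p
}
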