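#' Preprocessing configuration
#'
#' @param baseline_order polynomial order of the fluorescence baseline fit
#'   (default 3).
#' @param baseline_max_iter maximum iterations of the iterative clipping fit.
#' @param baseline_tol relative-change convergence tolerance.
#' @param reference_si_line crystalline-silicon calibration line, cm^-1.
#' @param crop_range closed fingerprint interval kept after cropping, cm^-1.
#' @param normalize logical, apply unit-L2 vector normalization.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(baseline_order = 3, baseline_max_iter = 250,
                              baseline_tol = 1e-4, reference_si_line = 520.7,
                              crop_range = c(600, 1800), normalize = TRUE) {
  stopifnot(baseline_order >= 0, baseline_max_iter >= 1, baseline_tol > 0,
            length(crop_range) == 2, crop_range[1] < crop_range[2])
  structure(list(baseline_order = as.integer(baseline_order),
                 baseline_max_iter = as.integer(baseline_max_iter),
                 baseline_tol = baseline_tol,
                 reference_si_line = reference_si_line,
                 crop_range = crop_range, normalize = isTRUE(normalize)),
            class = "preprocess_config")
}

#' Diffraction-limited laser spot diameter
#'
#' `1.22 * wavelength / NA`, the Rayleigh-criterion diameter of a focused
#' laser spot.
#'
#' @param wavelength_nm excitation wavelength in nm.
#' @param numerical_aperture objective NA (0 < NA <= 1.5).
#' @return spot diameter in nm.
#' @examples
#' spot_diameter(532, 0.90)  # ~721 nm
#' @export
spot_diameter <- function(wavelength_nm, numerical_aperture) {
  if (wavelength_nm <= 0) stop("`wavelength_nm` must be positive")
  if (numerical_aperture <= 0 || numerical_aperture > 1.5)
    stop("`numerical_aperture` must be in (0, 1.5]")
  1.22 * wavelength_nm / numerical_aperture
}

#' Rigid axis calibration against the silicon line
#'
#' Translates the shift axis by `reference - measured_si_line` so the
#' measured crystalline-silicon line lands on its reference position
#' (520.7 cm^-1). Offsets beyond 10 cm^-1 signal an instrument fault.
#'
#' @param x a [raman_spectrum()] or [raman_set()].
#' @param measured_si_line observed silicon line position, cm^-1.
#' @param reference reference position, cm^-1.
#' @return object of the same class with translated shifts.
#' @export
calibrate_axis <- function(x, measured_si_line, reference = 520.7) {
  offset <- reference - measured_si_line
  if (abs(offset) > 10)
    stop("silicon line offset exceeds 10 cm-1; check the instrument")
  UseMethod("calibrate_axis")
}

#' @export
calibrate_axis.raman_spectrum <- function(x, measured_si_line,
                                          reference = 520.7) {
  x$shifts <- x$shifts + (reference - measured_si_line)
  x
}

#' @export
calibrate_axis.raman_set <- function(x, measured_si_line, reference = 520.7) {
  x$shifts <- x$shifts + (reference - measured_si_line)
  x
}

# Interpolate a background spectrum onto `shifts`; the background grid must
# cover the target grid (no extrapolation).
interp_background <- function(bg, shifts) {
  stopifnot(inherits(bg, "raman_spectrum"))
  if (min(bg$shifts) > min(shifts) || max(bg$shifts) < max(shifts))
    stop("background grid does not cover the spectrum grid")
  stats::approx(bg$shifts, bg$intensities, xout = shifts)$y
}

#' Subtract the substrate background
#'
#' Subtracts a background spectrum (e.g. recorded on the bare CaF2 substrate)
#' from each spectrum, interpolating linearly when the grids differ.
#'
#' @param x a [raman_spectrum()] or [raman_set()].
#' @param bg a [raman_spectrum()] whose grid covers `x`.
#' @return object of the same class.
#' @export
subtract_background <- function(x, bg) UseMethod("subtract_background")

#' @export
subtract_background.raman_spectrum <- function(x, bg) {
  x$intensities <- x$intensities - interp_background(bg, x$shifts)
  x
}

#' @export
subtract_background.raman_set <- function(x, bg) {
  b <- interp_background(bg, x$shifts)
  x$intensities <- sweep(x$intensities, 2, b)
  x
}

# Iterative polynomial baseline on an intensity matrix (rows = spectra).
# Modified polyfit: refit after clipping the working signal to the current
# fit, so peaks are progressively excluded; exact on peak-free polynomials.
baseline_matrix <- function(Y, shifts, order, max_iter, tol) {
  u <- (shifts - mean(shifts)) / (diff(range(shifts)) / 2)
  basis <- qr.Q(qr(outer(u, 0:order, `^`)))       # orthonormal columns
  proj <- function(W) (W %*% basis) %*% t(basis)  # row-wise LS polynomial fit
  work <- Y
  fit <- proj(work)
  for (it in seq_len(max_iter)) {
    work <- pmin(work, fit)
    new_fit <- proj(work)
    delta <- max(abs(new_fit - fit)) / max(abs(fit), 1e-300)
    fit <- new_fit
    if (delta < tol) return(list(baseline = fit, converged = TRUE))
  }
  warning("baseline fit did not converge within `baseline_max_iter` iterations")
  list(baseline = fit, converged = FALSE)
}

#' Fluorescence baseline correction by iterative polynomial fitting
#'
#' Fits an order-`baseline_order` polynomial (default cubic) by iterative
#' clipping: points above the current fit are pulled down to it and the fit
#' repeated until the relative change falls below `baseline_tol`. Peak-free
#' polynomial inputs of degree <= order are removed exactly (to solver
#' tolerance).
#'
#' @param x a [raman_spectrum()] or [raman_set()].
#' @param cfg a [preprocess_config()].
#' @return object of the same class with the baseline removed; the estimated
#'   baseline is attached as attribute `"baseline"` (vector or matrix).
#' @export
baseline_correct <- function(x, cfg = preprocess_config()) {
  UseMethod("baseline_correct")
}

#' @export
baseline_correct.raman_spectrum <- function(x, cfg = preprocess_config()) {
  if (length(x$shifts) <= cfg$baseline_order + 1)
    stop("spectrum shorter than baseline_order + 2 points")
  res <- baseline_matrix(matrix(x$intensities, nrow = 1), x$shifts,
                         cfg$baseline_order, cfg$baseline_max_iter,
                         cfg$baseline_tol)
  x$intensities <- x$intensities - drop(res$baseline)
  attr(x, "baseline") <- drop(res$baseline)
  x
}

#' @export
baseline_correct.raman_set <- function(x, cfg = preprocess_config()) {
  if (n_spectra(x) == 0) return(x)
  if (length(x$shifts) <= cfg$baseline_order + 1)
    stop("spectra shorter than baseline_order + 2 points")
  res <- baseline_matrix(x$intensities, x$shifts, cfg$baseline_order,
                         cfg$baseline_max_iter, cfg$baseline_tol)
  x$intensities <- x$intensities - res$baseline
  attr(x, "baseline") <- res$baseline
  x
}

#' Crop spectra to a closed shift interval
#'
#' @param x a [raman_spectrum()] or [raman_set()].
#' @param range closed interval in cm^-1 (default the 600-1800 fingerprint).
#' @return object of the same class restricted to `range`.
#' @export
crop_spectra <- function(x, range = c(600, 1800)) UseMethod("crop_spectra")

#' @export
crop_spectra.raman_spectrum <- function(x, range = c(600, 1800)) {
  keep <- x$shifts >= range[1] & x$shifts <= range[2]
  x$shifts <- x$shifts[keep]; x$intensities <- x$intensities[keep]
  x
}

#' @export
crop_spectra.raman_set <- function(x, range = c(600, 1800)) {
  keep <- x$shifts >= range[1] & x$shifts <= range[2]
  x$shifts <- x$shifts[keep]
  x$intensities <- x$intensities[, keep, drop = FALSE]
  x
}

#' Vector (unit-L2) normalization
#'
#' Scales each spectrum to unit Euclidean norm so intensities are comparable
#' across acquisitions. Idempotent; errors on an all-zero spectrum.
#'
#' @param x a [raman_spectrum()] or [raman_set()].
#' @return object of the same class with unit-norm intensities.
#' @export
vector_normalize <- function(x) UseMethod("vector_normalize")

#' @export
vector_normalize.raman_spectrum <- function(x) {
  nrm <- sqrt(sum(x$intensities^2))
  if (nrm == 0) stop("cannot normalize an all-zero spectrum")
  x$intensities <- x$intensities / nrm
  x
}

#' @export
vector_normalize.raman_set <- function(x) {
  if (n_spectra(x) == 0) return(x)
  nrm <- sqrt(rowSums(x$intensities^2))
  if (any(nrm == 0)) stop("cannot normalize an all-zero spectrum")
  x$intensities <- x$intensities / nrm
  x
}

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: axis calibration (if a measured silicon line is given)
#' -> substrate background subtraction (if a background is given) -> crop to
#' the fingerprint interval -> iterative polynomial baseline correction ->
#' vector normalization. Every output spectrum has unit Euclidean norm and an
#' axis inside the crop interval; the configuration used is attached so
#' downstream blind prediction can verify it matches training.
#'
#' @param set a raw [raman_set()].
#' @param bg optional background [raman_spectrum()].
#' @param measured_si_line optional observed silicon line, cm^-1.
#' @param cfg a [preprocess_config()].
#' @return the preprocessed [raman_set()] (stage `"preprocessed"`), with
#'   attribute `"pp_config"`.
#' @export
preprocess_spectra <- function(set, bg = NULL, measured_si_line = NULL,
                               cfg = preprocess_config()) {
  stopifnot(inherits(set, "raman_set"))
  if (n_spectra(set) == 0) {
    attr(set, "pp_config") <- cfg
    return(set)
  }
  if (any(set$meta$stage != "raw"))
    stop("`set` must contain raw spectra")
  if (!is.null(measured_si_line))
    set <- calibrate_axis(set, measured_si_line, cfg$reference_si_line)
  if (!is.null(bg)) set <- subtract_background(set, bg)
  set <- crop_spectra(set, cfg$crop_range)
  set <- baseline_correct(set, cfg)
  if (cfg$normalize) set <- vector_normalize(set)
  set$meta$stage <- "preprocessed"
  attr(set, "baseline") <- NULL
  attr(set, "pp_config") <- cfg
  set
}
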