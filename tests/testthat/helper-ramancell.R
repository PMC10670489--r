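# Shared fixtures, built in code.

# Coarse axis (301 points) keeps the small-network tests fast; slices of 100
# points are still deep enough for the 25-layer convolution stack.
tiny_axis <- function() seq(600, 1800, by = 4)

# A small, clean (no corruption) preprocessed set for classifier unit tests.
tiny_clean_set <- function(seed = 1, n_cells = 8, noise_sd = 0.02) {
  cfg <- sim_config(n_cells_per_class = n_cells, spectra_per_cell = 5,
                    axis = tiny_axis(), noise_sd = noise_sd, seed = seed)
  preprocess_spectra(generate_dataset(cfg))
}

# Baseline-free configuration: spectra are band sums plus optional noise.
bare_config <- function(axis = tiny_axis(), noise_sd = 0, cell_effect_sd = 0,
                        ...) {
  sim_config(axis = axis, noise_sd = noise_sd,
             baseline_coeffs_range = list(c(0, 0), c(0, 0), c(0, 0), c(0, 0)),
             cell_effect_sd = cell_effect_sd, ...)
}

# The full-scale study conditions (40 cells x 5 spectra per class, 10%
# corruption), run once per test session and cached: several acceptance
# checks share this pipeline.
.pipeline_cache <- new.env(parent = emptyenv())

study_pipeline <- function() {
  if (is.null(.pipeline_cache$res)) {
    cfg <- sim_config(n_cells_per_class = 40, spectra_per_cell = 5,
                      outlier_fraction = 0.1, seed = 42)
    raw <- generate_dataset(cfg)
    pp <- preprocess_spectra(raw)
    om <- fit_outlier_model(pp, n_components = 5)
    flagged <- flag_outliers(pp, om, rule = "either")
    .pipeline_cache$res <- list(raw = raw, pp = pp, model = om,
                                flagged = flagged,
                                clean = remove_outliers(flagged))
  }
  .pipeline_cache$res
}
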