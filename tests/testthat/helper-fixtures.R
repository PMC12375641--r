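# Small in-code fixtures shared across test files.

# cubic grid with every voxel set in the mask
make_uniform_case <- function(n = 5, dose = 5000, spacing = 2) {
  g <- dose_grid(array(dose, c(n, n, n)), spacing)
  m <- structure_mask("S", array(TRUE, c(n, n, n)), voxel_volume_cc(g))
  list(grid = g, mask = m)
}

# linear ramp 0 -> dmax along the first axis, full-cube mask
make_ramp_case <- function(n = 20, dmax = 6000, spacing = 2) {
  vals <- array(rep(seq(0, dmax, length.out = n), times = n * n), c(n, n, n))
  g <- dose_grid(vals, spacing)
  m <- structure_mask("Ramp", array(TRUE, c(n, n, n)), voxel_volume_cc(g))
  list(grid = g, mask = m)
}

# random differential DVH with n_bins bins of the given width
random_dvh <- function(n_bins = 40, bin_width = 10, total = 50,
                       structure = "S") {
  vols <- stats::runif(n_bins)
  vols <- vols / sum(vols) * total
  differential_dvh(seq(0, by = bin_width, length.out = n_bins + 1) + 3000,
                   vols, structure = structure)
}

# single-bin (uniform) DVH centred on `dose`
uniform_dvh <- function(dose, volume = 10, width = 1, structure = "S") {
  differential_dvh(c(dose - width / 2, dose + width / 2), volume,
                   structure = structure)
}

fibrosis_model <- function() default_models()[[
  "Lungs:Symptomatic or radiographic fibrosis (>6 months)"]]
pneumonitis_model <- function() default_models()[[
  "Lungs:Symptomatic or radiographic pneumonitis (<=6 months)"]]
esophagitis_model <- function() default_models()[[
  "Esophagus:Esophagitis grade >= 2"]]
ptv_model <- function(gamma50 = 1.5) default_models(gamma50_ptv = gamma50)[[
  "PTV:Tumor control"]]
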