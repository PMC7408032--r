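# Small, fast configurations used across tests.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_subjects_per_class = 3L, n_replicates_per_subject = 4L,
         outlier_fraction = 0, seed = 11L),
    list(...))
  do.call(sim_config, args)
}

# all artifact channels off: inject_artifacts becomes the identity
noiseless_config <- function(...) {
  args <- utils::modifyList(
    list(subject_sd = 0, scatter_slope_sd = 0, scatter_offset_sd = 0,
         baseline_sd = 0, noise_sd = 0, water_vapor_amplitude = 0),
    list(...))
  do.call(tiny_config, args)
}

# single Gaussian band at the amide-I position, no class effects
one_band <- function(center = 1655, width = 18, amplitude = 0.5) {
  list(band_spec(center, width, amplitude))
}

random_dataset <- function(n = 8, p = 40, seed = 5) {
  set.seed(seed)
  spectral_dataset(seq(1000, by = 2, length.out = p),
                   matrix(rnorm(n * p, mean = 1, sd = 0.2), n))
}
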