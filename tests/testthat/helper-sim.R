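# Small, fast simulation configurations for unit tests. Acceptance tests use
# the package defaults.

tiny_config <- function(...) {
  over <- list(...)
  base <- list(field_shape_px = c(96L, 96L), n_z = 3L,
               n_responsive = 6L, n_unresponsive = 2L,
               n_dendrites = 2L, rng_seed = 42L)
  base[names(over)] <- over
  do.call(sim_config, base)
}

# a clean single-punctum config for exactness checks
clean_config <- function(...) {
  tiny_config(n_responsive = 1L, n_unresponsive = 0L,
              tau_mean_s = 90, tau_sd_s = 0,
              residual_fraction_range = c(0, 0),
              shot_noise = FALSE, read_noise_sd = 0,
              drift_step_px = 0L, ...)
}
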