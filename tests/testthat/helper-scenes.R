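# Shared synthetic scenes, built once per test run and cached, so the
# heavier benchmark computations are not repeated across test files.

.scene_cache <- new.env(parent = emptyenv())

# Default benchmark: the full 300-spot scene at the default study
# conditions, quantified end to end.
benchmark_run <- function() {
  if (is.null(.scene_cache$bench)) {
    .scene_cache$bench <- run_pipeline(seed = 1)
  }
  .scene_cache$bench
}

# Small noiseless configuration for conservation checks.
noiseless_config <- function(n_spots = 40) {
  simulation_config(
    n_spots = n_spots, image_dim = c(500, 500), noise_sd = 0,
    background_level = 0, min_separation_px = 25, edge_margin_px = 20,
    gel_scale_factors = c(case = 1, control = 1)
  )
}

noiseless_scene <- function() {
  if (is.null(.scene_cache$noiseless)) {
    .scene_cache$noiseless <- simulate_gel_scene(noiseless_config(),
                                                 seed = 11)
  }
  .scene_cache$noiseless
}
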