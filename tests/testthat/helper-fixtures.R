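# Shared synthetic fixtures, generated once per test run.

gs_test_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_atlas(n_rows = 8, n_cols = 8, n_species = 40,
                               seed = 99)
    }
    cache
  }
})

# Uniform-effort covariate table for a small grid (no trend, no innovations):
# handy when a test needs land use but no climate change.
gs_flat_covariates <- function(grid, n_periods = 1, seed = 5) {
  simulate_covariates(grid, n_periods,
                      trend = list(temperature = 0, precipitation = 0,
                                   seminatural_loss = 0),
                      innovation_sd = list(temperature = 0, precipitation = 0),
                      seed = seed)
}

# Random species sets over a fixed alphabet, for set-based property tests.
gs_random_sets <- function(n, alphabet = paste0("s", 1:12), seed = 1) {
  set.seed(seed)
  replicate(n, sample(alphabet, sample(0:8, 1)), simplify = FALSE)
}
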