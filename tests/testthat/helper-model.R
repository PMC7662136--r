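# One full default model run shared across the acceptance checks that need
# it (population medians and exceedance probabilities).
.model_cache <- new.env(parent = emptyenv())
default_model <- function(n_draws = 1e4, seed = 20) {
  key <- paste0("m", n_draws, "_", seed)
  if (is.null(.model_cache[[key]])) {
    .model_cache[[key]] <- run_full_model(n_draws = n_draws, seed = seed)
  }
  .model_cache[[key]]
}
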