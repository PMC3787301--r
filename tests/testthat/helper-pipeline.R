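# The default-condition study run is expensive; compute it once per test
# session and share it across the tests that measure recovery.
.run_cache <- new.env(parent = emptyenv())

default_study_run <- function() {
  if (is.null(.run_cache$run))
    .run_cache$run <- run_pipeline(simulation_config(seed = 1L))
  .run_cache$run
}
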