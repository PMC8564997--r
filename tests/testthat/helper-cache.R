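# One full default-design experiment, computed lazily and shared by every
# test that needs default study conditions.

.report_cache <- new.env(parent = emptyenv())

cached_default_report <- function() {
  if (is.null(.report_cache$default)) {
    .report_cache$default <- run_experiment(simulation_config(seed = 20260920))
  }
  .report_cache$default
}
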