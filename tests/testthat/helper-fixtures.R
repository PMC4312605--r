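# Shared small synthetic fixture, built once per test run.

small_config <- function(seed = 42) {
  sim_config(seed = seed, n_reads_per_library = 20000,
             n_conserved_mirnas = 12, n_novel_precursors = 4,
             genome_length = 30000, n_transcripts = 4)
}

.fixture_env <- new.env(parent = emptyenv())

small_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- run_pipeline(pipeline_config(
      simulation = small_config()))
  }
  .fixture_env$bundle
}

small_refs <- function() {
  if (is.null(.fixture_env$refs)) {
    .fixture_env$refs <- build_references(small_config())
  }
  .fixture_env$refs
}
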