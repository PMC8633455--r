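# Shared simulated fixtures, built once per test session. The small
# bundle keeps unit tests quick; the full-scale bundle (study defaults)
# is reserved for the acceptance checks.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 101) {
  sim_config(seed = seed, library_depth = 15000, genome_length = 60000,
             n_genes = 60, n_known_mirnas = 16, n_novel_hairpins = 5,
             n_de_mirnas = 6, mrna_depth = 120000)
}

small_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- suppressMessages(simulate_dataset(small_config()))
  }
  .fixtures$sim
}

small_run <- function() {
  if (is.null(.fixtures$run)) {
    .fixtures$run <- suppressMessages(run_pipeline(small_sim()$bundle))
  }
  .fixtures$run
}

full_sim <- function() {
  if (is.null(.fixtures$full_sim)) {
    .fixtures$full_sim <- suppressMessages(
      simulate_dataset(sim_config(seed = 20260901)))
  }
  .fixtures$full_sim
}

full_run <- function() {
  if (is.null(.fixtures$full_run)) {
    .fixtures$full_run <- suppressMessages(
      run_pipeline(full_sim()$bundle))
  }
  .fixtures$full_run
}
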