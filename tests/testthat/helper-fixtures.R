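# Shared fixtures: small in-code cohorts and a memoised default pipeline run
# so the end-to-end acceptance properties do not recompute it per block.

write_tsv_text <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# Tiny deterministic cohort: 2 planted drivers (1 OCG, 1 TSG), few nulls.
tiny_sim <- function(seed = 11) {
  simulate_cohort(sim_config(
    n_tumor = 14, n_normal = 10, n_hypo_ocg = 1, n_hyper_tsg = 1,
    n_null_genes = 20, targets_per_process = 4, seed = seed))
}

.pipeline_cache <- new.env(parent = emptyenv())

# Default-condition cohort and full pipeline run, computed once per session.
default_run <- function() {
  if (is.null(.pipeline_cache$run)) {
    sim <- simulate_cohort(sim_config(seed = 2024))
    res <- suppressMessages(run_pipeline(sim, seed = 2024))
    .pipeline_cache$run <- list(sim = sim, res = res)
  }
  .pipeline_cache$run
}
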