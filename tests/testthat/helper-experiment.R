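# The full desk-scale replication experiment is expensive, and several
# acceptance checks read different facets of the same run, so it is
# computed once per test session on first use.
.experiment_cache <- new.env(parent = emptyenv())

acceptance_experiment <- function() {
  if (is.null(.experiment_cache$ex)) {
    .experiment_cache$ex <- run_phantom_experiment(
      seed = 1, include_noiseless_r1 = TRUE, verbose = FALSE)
  }
  .experiment_cache$ex
}
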