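# Desk-scale experiment fixtures for the property-based acceptance tests.
# The benchmark (method comparison, ablation, alignment) and the
# labeled-fraction sweep are each computed once per test session and shared
# by every test that consumes them.

.experiment_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function() {
  if (is.null(.experiment_cache$bench)) {
    .experiment_cache$bench <- run_transfer_benchmark(seeds = 1:5)
  }
  .experiment_cache$bench
}

acceptance_sweep <- function() {
  if (is.null(.experiment_cache$sweep)) {
    .experiment_cache$sweep <- run_sweep_study(seed = 1L)
  }
  .experiment_cache$sweep
}

mean_target_accuracy <- function(bench, meth) {
  with(bench$accuracy, mean(accuracy[method == meth & split == "target_test"]))
}
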