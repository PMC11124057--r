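# Shared synthetic dataset, generated once per test run.
.desolv_test_cache <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.desolv_test_cache$small)) {
    .desolv_test_cache$small <- gen_solubility_dataset(
      generator_config(seed = 42, n_records = 240))
  }
  .desolv_test_cache$small
}
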