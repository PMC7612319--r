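# The worked health impact fixture at R = 5000 is expensive to sample
# (each dose-response draw refits the curve), so it is built once per test
# run and shared.
.fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function() {
  if (is.null(.fixture_cache$ex)) {
    cfg <- health_model_config()
    ex <- run_example(cfg, R = 5000, seed = 2026, mode = "estimation")
    .fixture_cache$ex <- list(
      config = cfg,
      inputs = ex$inputs,
      y = ex$outputs,
      nb = net_benefit(as.numeric(ex$outputs),
                       decision_spec("threshold", threshold = cfg$k)))
  }
  .fixture_cache$ex
}
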