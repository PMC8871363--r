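# Scaled-down pilot of the full study, shared by the acceptance tests.
# Trained once per test run and cached; the configuration (10 genes, window
# 20, 30 epochs, batch 128, hidden size 16) is the package's pilot-scale
# stand-in for the hours-scale full study.
.pilot_cache <- new.env(parent = emptyenv())

pilot_architectures <- c("FullyConnected", "FullyRepressed",
                         "MasterRegulator", "SparseConnection")

pilot_study <- function() {
  if (!is.null(.pilot_cache$res)) {
    return(.pilot_cache$res)
  }
  cfg <- darnn_config(T = 20, encoder_hidden = 16, decoder_hidden = 16,
                      batch_size = 128, epochs = 30, learning_rate = 2e-3,
                      seed = 1)
  res <- lapply(pilot_architectures, function(arch) {
    spec <- build_architecture(arch, N = 10, seed = 11)
    traces <- standard_scale(simulate_grn(spec, seed = 21))
    models <- train_parallel(traces, cfg)
    rmse <- rmse_table(models, traces)
    list(spec = spec, traces = traces, models = models, rmse = rmse,
         attention = extract_input_attention(models, traces))
  })
  names(res) <- pilot_architectures
  .pilot_cache$res <- res
  res
}
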