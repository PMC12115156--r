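# Lazily trained models shared across test files (training is expensive;
# the easy-contrast model is reused by the robustness-harness tests).

.model_cache <- new.env(parent = emptyenv())

tiny_trained <- function(delta) {
  key <- sprintf("d%s", delta)
  if (!is.null(.model_cache[[key]])) return(.model_cache[[key]])
  spec <- scene_spec(image_size = 160L, contrast_delta = delta)
  train <- generate_dataset(200, spec, seed = 100)
  val <- generate_dataset(50, spec, seed = 9000)
  cfg <- run_config("tiny", seed = 0L)
  model <- seanet_train(train, cfg)
  out <- list(model = model, val = val)
  .model_cache[[key]] <- out
  out
}
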