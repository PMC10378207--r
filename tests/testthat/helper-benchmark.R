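# Shared end-to-end benchmark run: the full LOSO evaluation on the default
# synthetic dataset is expensive, so it is trained once and reused by the
# tests that inspect it (accuracy, reproducibility, Grad-CAM localization).
.benchEnv <- new.env(parent = emptyenv())

benchmarkConditions <- function() {
  list(spec = SyntheticSpec(seed = 7L),
       trainConfig = TrainConfig(epochs = 30L, seed = 1L),
       netConfig = NetConfig(nClasses = 3L))
}

benchmarkRun <- function() {
  if (is.null(.benchEnv$run)) {
    cond <- benchmarkConditions()
    ds <- makeDataset(cond$spec)
    rep <- evaluateLoso(ds, cond$trainConfig, cond$netConfig,
                        returnModels = TRUE)
    .benchEnv$run <- list(ds = ds, report = rep, cond = cond)
  }
  .benchEnv$run
}
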