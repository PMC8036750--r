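# The full-scale (500-ROI) benign-vs-malignant pipeline run is shared by
# several acceptance checks; run it once per session and cache the result.
.fullRunCache <- new.env(parent = emptyenv())

fullPipelineRun <- function() {
  if (!is.null(.fullRunCache$res)) return(.fullRunCache$res)
  cfg <- pipelineConfig(outputDir = file.path(tempdir(), "stainfos_full"),
                        runId = "acceptance", seed = 20260925L,
                        nPerClass = 250L,
                        bilstm = list(epochs = 15L, patience = 5L))
  res <- runPipeline(cfg)
  .fullRunCache$res <- list(cfg = cfg, res = res)
  .fullRunCache$res
}

# small smoke-scale config used by pipeline unit tests
smokeConfig <- function(dir = tempfile("smoke_"), seed = 11L, ...) {
  pipelineConfig(outputDir = dir, runId = "r1", seed = seed,
                 nPerClass = 6L,
                 models = c("boosting", "dc_bilstm"),
                 bilstm = list(epochs = 4L, hidden = 8L), ...)
}
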