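# Memoized models shared across test files so each is trained at most once
# per test run.

.modelCache <- new.env(parent = emptyenv())

# Small model for pipeline/IO contract tests: quick to train, accuracy is
# not asserted on it.
tinyTrainedModel <- function() {
  if (!is.null(.modelCache$tiny)) return(.modelCache$tiny)
  data <- makePatchDataset(sceneConfig(cpdLambda = 1, seed = 900L),
                           nPerCategory = 60)
  net <- buildWSCNet(seed = 4)
  net <- trainWSCNet(net, data, trainConfig(learningRate = 5e-3,
                                            batchSize = 64L,
                                            maxEpochs = 3L, seed = 5L))
  .modelCache$tiny <- net
  net
}

# The desk-scale benchmark model: ~12k patches (3000 per category), batch
# 256, 10 epochs. Returns the model together with its held-out test split.
benchmarkModel <- function() {
  if (!is.null(.modelCache$bench)) return(.modelCache$bench)
  data <- makePatchDataset(sceneConfig(cpdLambda = 1, seed = 100L),
                           nPerCategory = 3000)
  net <- buildWSCNet(seed = 1)
  net <- trainWSCNet(net, data,
                     trainConfig(learningRate = 5e-3, batchSize = 256L,
                                 maxEpochs = 10L, patience = 3L, seed = 2L))
  .modelCache$bench <- list(model = net, data = data)
  .modelCache$bench
}
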