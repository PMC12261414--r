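# small random builders shared across test files

randomSample <- function(n = 5, m = 3, nTypes = 2, label = 1L, id = "s") {
  milSample(matrix(rnorm(n * m), n, m),
            sample.int(nTypes, n, replace = TRUE), label, id)
}

# a model with random (untrained) parameters; seeds vary by call site
randomModel <- function(m = 3, C = 2, mode = "HA", d = 4, layers = 1,
                        binary = C == 2, seed = 1, attScale = 1) {
  mod <- milModel(inputDim = m, nClasses = C, mode = mode, hiddenDim = d,
                  nHiddenLayers = layers, binaryHead = binary, seed = seed)
  # inflate the attention vectors so softmaxes are far from uniform
  mod@params$w <- mod@params$w * attScale / 0.01
  mod@params$v <- mod@params$v * attScale / 0.01
  mod
}

quickTrain <- function(nEpochs = 15, batchSize = 0, lr = 5e-3, seed = 1)
  trainConfig(learningRate = lr, nEpochs = nEpochs, batchSize = batchSize,
              seed = seed)

# small two-class cohort with a clear expression signal; fast to fit
signalCohort <- function(seed = 1, S = c(10, 10), m = 12, I = 4)
  simulateCohort(S = S, nCellTypes = I, nFeatures = m,
                 cellsPerSample = c(10, 20), effectSize = 2,
                 nSignalFeatures = 6, seed = seed)
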