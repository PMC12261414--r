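#' Training configuration
#'
#' Settings for the mini-batch Adam optimizer that minimizes the
#' cross-entropy objective.
#'
#' @param learningRate step size (default 1e-3).
#' @param nEpochs passes over the cohort.
#' @param batchSize samples per mini-batch; `0` means full batch.
#' @param weightDecay L2 penalty coefficient applied to weight matrices
#'   (not biases).
#' @param earlyStopPatience stop after this many epochs without training-loss
#'   improvement; `0` disables early stopping.
#' @param seed RNG seed controlling batch shuffling.
#' @return A list of class `milTrainConfig`.
#' @export
trainConfig <- function(learningRate = 1e-3, nEpochs = 50L, batchSize = 8L,
                        weightDecay = 0, earlyStopPatience = 0L, seed = 1L) {
  stopifnot(learningRate >= 0, nEpochs >= 1, weightDecay >= 0)
  structure(list(learningRate = learningRate, nEpochs = as.integer(nEpochs),
                 batchSize = as.integer(batchSize), weightDecay = weightDecay,
                 earlyStopPatience = as.integer(earlyStopPatience),
                 seed = as.integer(seed)),
            class = "milTrainConfig")
}

#' Fit a model to a cohort by mini-batch gradient descent
#'
#' Minimizes the cross-entropy loss with Adam. The full forward/backward
#' pass runs in compiled code; batch shuffling consumes only R's RNG, so a
#' fit is reproducible from the two seeds (model initialization seed and
#' `config$seed`).
#'
#' @param object an initialized [MILModel] (see [milModel()]).
#' @param cohort a [MILCohort] with at least two samples and both/all
#'   classes present.
#' @param config a [trainConfig()].
#' @param ... unused.
#' @return The fitted [MILModel]; the attribute `"lossTrace"` on the result
#'   holds the mean training loss per epoch.
#' @examples
#' co <- simulateCohort(S = c(5, 5), nCellTypes = 3, nFeatures = 8,
#'                      cellsPerSample = c(10, 20), seed = 1)
#' mod <- milModel(8, 2, mode = "CTA", hiddenDim = 4,
#'                 cellTypeNames = cellTypeNames(co), classNames = classNames(co))
#' fit <- fitModel(mod, co, trainConfig(nEpochs = 5))
#' @export
setMethod("fitModel", "MILModel", function(object, cohort, config = trainConfig(), ...) {
  stopifnot(is(cohort, "MILCohort"), inherits(config, "milTrainConfig"))
  if (nSamples(cohort) < 2L)
    stop("need at least 2 samples to fit")
  if (length(unique(sampleLabels(cohort))) < 2L)
    stop("need at least 2 classes present to fit")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)
  res <- .fitCpp(.cohortMatrices(cohort), .cohortTypes(cohort),
                 sampleLabels(cohort) - 1L, object@params,
                 .cppConfig(object), config$learningRate, config$nEpochs,
                 config$batchSize, config$weightDecay,
                 config$earlyStopPatience)
  if (!isTRUE(res$ok)) {
    tr <- res$loss[!is.na(res$loss)]
    stop("non-finite training loss at epoch ", length(tr) + 1L,
         "; last finite losses: ",
         paste(signif(utils::tail(tr, 3), 4), collapse = ", "),
         " (learningRate=", config$learningRate, ")", call. = FALSE)
  }
  object@params <- res$params
  if (!length(object@cellTypeNames))
    object@cellTypeNames <- cellTypeNames(cohort)
  if (!length(object@classNames))
    object@classNames <- classNames(cohort)
  attr(object, "lossTrace") <- res$loss[!is.na(res$loss)]
  object
})

#' One-call model construction and fitting
#'
#' Convenience wrapper that builds a [milModel()] sized for `cohort` and
#' fits it.
#'
#' @param cohort a [MILCohort].
#' @param mode aggregation architecture (see [MILModel]).
#' @param hiddenDim,nHiddenLayers,nonlinearity,binaryHead passed to
#'   [milModel()].
#' @param config a [trainConfig()].
#' @param seed initialization seed for the parameters.
#' @return A fitted [MILModel].
#' @export
fitMIL <- function(cohort, mode = "CTA", hiddenDim = 32L, nHiddenLayers = 1L,
                   nonlinearity = "relu",
                   binaryHead = length(classNames(cohort)) == 2L,
                   config = trainConfig(), seed = 1L) {
  mod <- milModel(inputDim = length(cohort@featureNames),
                  nClasses = length(classNames(cohort)),
                  mode = mode, hiddenDim = hiddenDim,
                  nHiddenLayers = nHiddenLayers, nonlinearity = nonlinearity,
                  binaryHead = binaryHead,
                  cellTypeNames = cellTypeNames(cohort),
                  classNames = classNames(cohort), seed = seed)
  fitModel(mod, cohort, config)
}

#' Build a trainer callable for the permutation test
#'
#' Returns a function `(cohort, seed) -> fitted MILModel` that freezes the
#' architecture and optimizer settings, so [permutationTest()] can refit
#' from a fresh initialization on each label permutation.
#'
#' @inheritParams fitMIL
#' @return A function of `(cohort, seed)`.
#' @export
milTrainer <- function(mode = "CTA", hiddenDim = 32L, nHiddenLayers = 1L,
                       nonlinearity = "relu", binaryHead = TRUE,
                       config = trainConfig()) {
  force(mode); force(config)
  function(cohort, seed) {
    cfg <- config
    cfg$seed <- seed
    fitMIL(cohort, mode = mode, hiddenDim = hiddenDim,
           nHiddenLayers = nHiddenLayers, nonlinearity = nonlinearity,
           binaryHead = binaryHead, config = cfg, seed = seed)
  }
}
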