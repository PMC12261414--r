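#' Classification metrics on predicted probabilities
#'
#' Computes AUC, F1, accuracy, precision and recall. For binary tasks
#' (C = 2) the F1/precision/recall refer to the positive class (class 2)
#' at a 0.5 threshold and the AUC uses the positive-class probability. For
#' C > 2 the AUC is one-vs-rest macro-averaged, F1/precision/recall are
#' macro-averaged, and classes are assigned by argmax.
#'
#' @param probs numeric matrix, samples x classes.
#' @param labels integer vector of 1-based class labels.
#' @return Named numeric vector `c(auc, f1, accuracy, precision, recall)`.
#' @examples
#' evaluateMetrics(cbind(c(.1, .2, .7), c(.9, .8, .3)), c(2L, 2L, 1L))
#' @export
evaluateMetrics <- function(probs, labels) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  C <- ncol(probs)
  if (length(unique(labels)) < 2L)
    stop("AUC is undefined for a single-class label vector", call. = FALSE)
  pred <- max.col(probs, ties.method = "first")
  acc <- mean(pred == labels)
  prf <- function(truth, call) {
    tp <- sum(truth & call); fp <- sum(!truth & call); fn <- sum(truth & !call)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }
  if (C == 2L) {
    auc <- .binaryAUC(probs[, 2L], labels == 2L)
    x <- prf(labels == 2L, pred == 2L)
  } else {
    aucs <- vapply(seq_len(C), function(c) {
      if (length(unique(labels == c)) < 2L) return(NA_real_)
      .binaryAUC(probs[, c], labels == c)
    }, numeric(1))
    auc <- mean(aucs, na.rm = TRUE)
    x <- rowMeans(vapply(seq_len(C),
                         function(c) prf(labels == c, pred == c),
                         numeric(3)))
  }
  c(auc = auc, f1 = x[3L], accuracy = acc, precision = x[1L], recall = x[2L])
}

.binaryAUC <- function(score, positive) {
  as.numeric(pROC::auc(pROC::roc(response = factor(positive,
                                                   levels = c(FALSE, TRUE)),
                                 predictor = score, quiet = TRUE,
                                 direction = "<")))
}

# stratified k-fold assignment: shuffle within class, deal round-robin
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Default hyperparameter grid
#'
#' @return A `data.frame` with columns `hiddenDim`, `nHiddenLayers`,
#'   `learningRate`, `weightDecay`, one row per candidate combination.
#' @export
defaultGrid <- function() {
  expand.grid(hiddenDim = c(32L, 64L), nHiddenLayers = c(1L, 2L),
              learningRate = c(1e-3, 1e-4), weightDecay = c(0, 1e-4))
}

# fit one grid point on a (sub)cohort and predict on held-out samples;
# returns probability matrix or NULL on failure
.fitPredict <- function(trainCo, testCo, mode, point, baseConfig, seed) {
  cfg <- baseConfig
  cfg$learningRate <- point$learningRate
  cfg$weightDecay <- point$weightDecay
  cfg$seed <- seed
  mod <- fitMIL(trainCo, mode = mode, hiddenDim = point$hiddenDim,
                nHiddenLayers = point$nHiddenLayers, config = cfg,
                seed = seed)
  predictProba(mod, testCo)
}

#' Repeated nested cross-validation
#'
#' Stratified outer folds estimate generalization; for every outer fold each
#' hyperparameter grid point is scored by the AUC of its stacked inner-fold
#' predictions on the outer-training split, the best point is refit on the
#' full outer-training split, and its outer-test predictions are stacked.
#' Metrics are computed once per repeat on the S stacked out-of-fold
#' predictions; the procedure is repeated with different fold seeds and
#' mean and standard deviation over repeats are reported. Hyperparameter
#' selection sees only inner folds, so outer-test data never influence it.
#'
#' A grid point whose fit fails is scored as AUC 0.5 (with a message); a
#' failing final refit yields uniform probabilities for that fold.
#'
#' @param cohort a [MILCohort] with at least `nOuter` samples.
#' @param mode aggregation architecture passed to [fitMIL()].
#' @param grid `data.frame` of candidate hyperparameters (see
#'   [defaultGrid()]).
#' @param nOuter,nInner outer and inner fold counts.
#' @param nRepeats number of repetitions with different fold seeds.
#' @param config base [trainConfig()]; learning rate and weight decay are
#'   overridden by the grid.
#' @param seed master seed; fold assignments and fit seeds derive from it.
#' @return A list of class `milCVResult`: `metrics` (per-repeat
#'   data.frame), `summary` (mean and sd per metric), `chosen` (selected
#'   grid row per repeat x outer fold), `folds` (per-repeat fold
#'   assignment), `stacked` (per-repeat out-of-fold probabilities),
#'   `seeds`, and the call configuration.
#' @export
nestedCV <- function(cohort, mode = "CTA", grid = defaultGrid(),
                     nOuter = 10L, nInner = 5L, nRepeats = 10L,
                     config = trainConfig(), seed = 1L) {
  stopifnot(is(cohort, "MILCohort"), nrow(grid) >= 1L)
  S <- nSamples(cohort)
  if (S < nOuter) stop("cohort has fewer samples than outer folds")
  labs <- sampleLabels(cohort)
  repSeeds <- deriveSeeds(seed, nRepeats)
  metrics <- NULL
  chosen <- list()
  foldMaps <- list()
  stackedAll <- list()
  for (r in seq_len(nRepeats)) {
    set.seed(repSeeds[r])
    fold <- .stratifiedFolds(labs, nOuter)
    fitSeedPool <- sample.int(.Machine$integer.max - 1L,
                              nOuter * (nrow(grid) * nInner + 1L))
    seedIdx <- 0L
    nextSeed <- function() {
      seedIdx <<- seedIdx + 1L
      fitSeedPool[seedIdx]
    }
    stacked <- matrix(NA_real_, S, length(classNames(cohort)))
    chosenRep <- vector("list", nOuter)
    for (of in seq_len(nOuter)) {
      outTest <- which(fold == of)
      outTrain <- which(fold != of)
      if (!length(outTest)) next
      trLabs <- labs[outTrain]
      innerFold <- .stratifiedFolds(trLabs, nInner)
      gridAUC <- numeric(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        point <- grid[g, , drop = FALSE]
        innerProbs <- matrix(NA_real_, length(outTrain),
                             length(classNames(cohort)))
        okPoint <- TRUE
        for (inf in seq_len(nInner)) {
          inTest <- which(innerFold == inf)
          inTrain <- which(innerFold != inf)
          if (!length(inTest)) next
          pr <- tryCatch(
            .fitPredict(cohort[outTrain[inTrain]], cohort[outTrain[inTest]],
                        mode, point, config, nextSeed()),
            error = function(e) NULL)
          if (is.null(pr)) { okPoint <- FALSE; break }
          innerProbs[inTest, ] <- pr
        }
        gridAUC[g] <- if (!okPoint || anyNA(innerProbs)) {
          message("grid point ", g, " failed to train; scored as AUC 0.5")
          0.5
        } else {
          unname(evaluateMetrics(innerProbs, trLabs)["auc"])
        }
      }
      best <- which.max(gridAUC)
      chosenRep[[of]] <- cbind(grid[best, , drop = FALSE],
                               innerAUC = gridAUC[best], outerFold = of)
      pr <- tryCatch(
        .fitPredict(cohort[outTrain], cohort[outTest], mode,
                    grid[best, , drop = FALSE], config, nextSeed()),
        error = function(e) {
          message("outer refit failed; predicting uniform probabilities")
          matrix(1 / length(classNames(cohort)), length(outTest),
                 length(classNames(cohort)))
        })
      stacked[outTest, ] <- pr
    }
    met <- evaluateMetrics(stacked, labs)
    metrics <- rbind(metrics, data.frame(repeatId = r, t(met)))
    chosen[[r]] <- do.call(rbind, chosenRep)
    foldMaps[[r]] <- fold
    stackedAll[[r]] <- stacked
  }
  summaryTab <- data.frame(
    metric = c("auc", "f1", "accuracy", "precision", "recall"),
    mean = vapply(c("auc", "f1", "accuracy", "precision", "recall"),
                  function(k) mean(metrics[[k]]), numeric(1)),
    sd = vapply(c("auc", "f1", "accuracy", "precision", "recall"),
                function(k) stats::sd(metrics[[k]]), numeric(1)),
    row.names = NULL)
  structure(list(metrics = metrics, summary = summaryTab, chosen = chosen,
                 folds = foldMaps, stacked = stackedAll, seeds = repSeeds,
                 mode = normalizeMode(mode), nOuter = nOuter,
                 nInner = nInner, grid = grid, seed = seed),
            class = "milCVResult")
}

#' @export
print.milCVResult <- function(x, ...) {
  cat("Nested CV (", x$mode, "): ", nrow(x$metrics), " repeat(s), ",
      x$nOuter, " outer x ", x$nInner, " inner folds, grid of ",
      nrow(x$grid), "\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
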