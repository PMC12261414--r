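test_that("metrics match brute-force calculations", {
  # AUC by exhaustive positive-negative pair comparison: 2/3
  probs <- cbind(1 - c(0.9, 0.8, 0.3, 0.1), c(0.9, 0.8, 0.3, 0.1))
  labels <- c(2L, 2L, 1L, 2L)
  m <- evaluateMetrics(probs, labels)
  expect_equal(unname(m["auc"]), 2 / 3)
  # perfect separation
  p2 <- cbind(c(0.1, 0.2, 0.9), c(0.9, 0.8, 0.1))
  expect_equal(unname(evaluateMetrics(p2, c(2L, 2L, 1L))[c("auc", "f1")]),
               c(1, 1))
  # anti-correlated scores
  expect_equal(unname(evaluateMetrics(p2, c(1L, 1L, 2L))["auc"]), 0)
  expect_error(evaluateMetrics(p2, c(1L, 1L, 1L)), "single-class")
  # macro averaging over three classes, hand-checked
  p3 <- rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1),
              c(0.1, 0.1, 0.8), c(0.4, 0.5, 0.1))
  m3 <- evaluateMetrics(p3, c(1L, 2L, 3L, 1L))
  expect_equal(unname(m3["accuracy"]), 0.75)
  prec <- mean(c(1, 1 / 2, 1))      # per-class precision at argmax
  rec <- mean(c(1 / 2, 1, 1))       # per-class recall
  expect_equal(unname(m3["precision"]), prec)
  expect_equal(unname(m3["recall"]), rec)
})

test_that("stratified folds partition samples and balance classes", {
  set.seed(1)
  labels <- rep(c(1L, 2L), c(15, 35))
  fold <- hierMIL:::.stratifiedFolds(labels, 10)
  expect_equal(sort(unique(fold)), 1:10)
  expect_equal(as.vector(table(fold)), rep(5L, 10))
  # every fold receives at least one sample of the minority class or the
  # counts differ by at most one across folds
  perFold <- table(fold, labels)
  expect_true(all(abs(perFold[, 1] - 1.5) <= 0.5))
})

test_that("nested CV stacks every sample exactly once per repeat", {
  co <- signalCohort(seed = 21, S = c(10, 10))
  grid <- data.frame(hiddenDim = 4L, nHiddenLayers = 1L,
                     learningRate = 5e-3, weightDecay = 0)
  cv <- nestedCV(co, mode = "CTA", grid = grid, nOuter = 10, nInner = 3,
                 nRepeats = 2, config = quickTrain(nEpochs = 6), seed = 3)
  for (r in 1:2) {
    expect_false(anyNA(cv$stacked[[r]]))
    expect_equal(as.vector(table(cv$folds[[r]])), rep(2L, 10))
    # single grid point: it must be chosen in every fold
    expect_true(all(vapply(seq_len(10), function(f)
      cv$chosen[[r]]$hiddenDim[f] == 4L, logical(1))))
  }
  expect_equal(nrow(cv$metrics), 2)
  expect_true(all(cv$metrics$auc >= 0 & cv$metrics$auc <= 1))
  # reproducibility of the full protocol
  cv2 <- nestedCV(co, mode = "CTA", grid = grid, nOuter = 10, nInner = 3,
                  nRepeats = 2, config = quickTrain(nEpochs = 6), seed = 3)
  expect_identical(cv$metrics, cv2$metrics)
  expect_identical(cv$stacked, cv2$stacked)
})

test_that("hyperparameter selection ignores the outer-test samples", {
  # canary: corrupting an outer-test fold must not change the
  # hyperparameters selected for that fold (selection sees inner folds only)
  co <- signalCohort(seed = 22, S = c(8, 8))
  grid <- data.frame(hiddenDim = c(3L, 6L), nHiddenLayers = 1L,
                     learningRate = 5e-3, weightDecay = 0)
  base <- nestedCV(co, mode = "CTA", grid = grid, nOuter = 4, nInner = 3,
                   nRepeats = 1, config = quickTrain(nEpochs = 5), seed = 9)
  leakFold <- 2L
  idx <- which(base$folds[[1]] == leakFold)
  coLeak <- co
  for (i in idx) {
    s <- coLeak@samples[[i]]
    # plant a label-leaking feature in the held-out samples
    s@X[, 1] <- ifelse(s@label == 2L, 100, -100)
    coLeak@samples[[i]] <- s
  }
  leak <- nestedCV(coLeak, mode = "CTA", grid = grid, nOuter = 4, nInner = 3,
                   nRepeats = 1, config = quickTrain(nEpochs = 5), seed = 9)
  expect_identical(leak$folds[[1]], base$folds[[1]])
  pick <- function(cv) {
    tab <- cv$chosen[[1]][cv$chosen[[1]]$outerFold == leakFold,
                          c("hiddenDim", "innerAUC")]
    rownames(tab) <- NULL
    tab
  }
  expect_identical(pick(leak), pick(base))
})

test_that("a failing grid point is scored as AUC 0.5 and skipped", {
  co <- signalCohort(seed = 23, S = c(6, 6))
  # learning rate NA makes the fit error out for the second grid point
  grid <- data.frame(hiddenDim = c(4L, 4L), nHiddenLayers = 1L,
                     learningRate = c(5e-3, NA), weightDecay = 0)
  expect_message(
    cv <- nestedCV(co, mode = "CTA", grid = grid, nOuter = 3, nInner = 2,
                   nRepeats = 1, config = quickTrain(nEpochs = 4), seed = 2),
    "scored as AUC 0.5")
  expect_true(all(cv$chosen[[1]]$learningRate == 5e-3))
})
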