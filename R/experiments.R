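#' Robustness experiment: varying training size
#'
#' Repeatedly draws stratified random train/test splits at each training
#' fraction, fits the model on the training part and measures AUC on the
#' rest; the mean AUC per fraction is reported. A draw that leaves a
#' single-class training split is resampled (with a message).
#'
#' @param cohort a [MILCohort].
#' @param fractions training fractions to evaluate.
#' @param nSplits random splits per fraction.
#' @param mode,hiddenDim,nHiddenLayers,config model/optimizer settings
#'   (fixed across splits).
#' @param seed master seed.
#' @return `data.frame` with columns `fraction`, `meanAUC`, `sdAUC`,
#'   `nSplits`.
#' @export
experimentTrainSize <- function(cohort, fractions = c(0.25, 0.5, 0.75),
                                nSplits = 100L, mode = "CTA",
                                hiddenDim = 16L, nHiddenLayers = 1L,
                                config = trainConfig(), seed = 1L) {
  labs <- sampleLabels(cohort)
  S <- nSamples(cohort)
  seeds <- deriveSeeds(seed, length(fractions) * nSplits)
  res <- NULL
  k <- 0L
  for (f in fractions) {
    aucs <- numeric(nSplits)
    for (r in seq_len(nSplits)) {
      k <- k + 1L
      set.seed(seeds[k])
      repeat {
        # stratified draw: round f * n_c per class, at least one per class
        trIdx <- unlist(lapply(sort(unique(labs)), function(cl) {
          idx <- which(labs == cl)
          sample(idx, max(1L, round(f * length(idx))))
        }))
        teIdx <- setdiff(seq_len(S), trIdx)
        if (length(unique(labs[trIdx])) >= 2L &&
            length(unique(labs[teIdx])) >= 2L) break
        message("degenerate split resampled at fraction ", f)
      }
      fitSeed <- sample.int(.Machine$integer.max - 1L, 1L)
      cfg <- config; cfg$seed <- fitSeed
      mod <- fitMIL(cohort[trIdx], mode = mode, hiddenDim = hiddenDim,
                    nHiddenLayers = nHiddenLayers, config = cfg,
                    seed = fitSeed)
      aucs[r] <- unname(evaluateMetrics(predictProba(mod, cohort[teIdx]),
                                        labs[teIdx])["auc"])
    }
    res <- rbind(res, data.frame(fraction = f, meanAUC = mean(aucs),
                                 sdAUC = stats::sd(aucs), nSplits = nSplits))
  }
  res
}

# subsample ceil(fraction * N) cells (at least 1) from every bag
.subsampleCells <- function(cohort, fraction) {
  cohort@samples <- lapply(cohort@samples, function(s) {
    n <- nrow(s@X)
    keep <- sort(sample(n, max(1L, ceiling(fraction * n))))
    initialize(s, X = s@X[keep, , drop = FALSE], cellType = s@cellType[keep])
  })
  cohort
}

# relabel exactly ceil(fraction * N) cells per bag, uniformly over all types
.corruptAnnotations <- function(cohort, fraction, nTypes) {
  if (fraction <= 0) return(cohort)
  cohort@samples <- lapply(cohort@samples, function(s) {
    n <- nrow(s@X)
    k <- min(n, ceiling(fraction * n))
    idx <- sample(n, k)
    s@cellType[idx] <- sample.int(nTypes, k, replace = TRUE)
    s
  })
  cohort
}

#' Robustness experiment: varying cell counts
#'
#' Per repeat, independently subsamples the stated fraction of cells in
#' every bag (ceiling, at least one cell kept) and runs the nested CV
#' protocol on the reduced cohort; the mean stacked AUC per fraction is
#' reported. Fraction 1 reproduces the unperturbed CV.
#'
#' @param cohort a [MILCohort].
#' @param fractions cell fractions to retain.
#' @param nRepeats repeats with fresh subsampling and fold seeds.
#' @param ... passed to [nestedCV()] (mode, grid, fold counts, config).
#' @param seed master seed.
#' @return `data.frame` with columns `fraction`, `meanAUC`, `sdAUC`,
#'   `nRepeats`.
#' @export
experimentCellSubsample <- function(cohort, fractions = c(0.25, 0.5, 0.75),
                                    nRepeats = 10L, ..., seed = 1L) {
  seeds <- deriveSeeds(seed, 2L * length(fractions) * nRepeats)
  res <- NULL
  k <- 0L
  for (f in fractions) {
    aucs <- numeric(nRepeats)
    for (r in seq_len(nRepeats)) {
      k <- k + 1L
      co <- if (f >= 1) cohort else {
        set.seed(seeds[2L * k - 1L])
        .subsampleCells(cohort, f)
      }
      cv <- nestedCV(co, ..., nRepeats = 1L, seed = seeds[2L * k])
      aucs[r] <- cv$summary$mean[cv$summary$metric == "auc"]
    }
    res <- rbind(res, data.frame(fraction = f, meanAUC = mean(aucs),
                                 sdAUC = stats::sd(aucs),
                                 nRepeats = nRepeats))
  }
  res
}

#' Robustness experiment: randomized cell-type annotations
#'
#' Per repeat, reassigns the stated fraction of cells in every bag
#' (ceiling) a cell type drawn uniformly over the full vocabulary, then
#' runs the nested CV protocol; the mean stacked AUC per noise level is
#' reported. Noise injection and CV consume separate derived seed streams,
#' so the 0-noise rows reproduce the unperturbed CV bitwise under the same
#' master seed.
#'
#' @param cohort a [MILCohort].
#' @param noiseFracs fractions of cells to relabel (0 = unperturbed).
#' @param nRepeats repeats with fresh corruption and fold seeds.
#' @param ... passed to [nestedCV()].
#' @param seed master seed.
#' @return `data.frame` with columns `noise`, `meanAUC`, `sdAUC`,
#'   `nRepeats`.
#' @export
experimentAnnotationNoise <- function(cohort, noiseFracs = c(0, 0.25, 0.5),
                                      nRepeats = 10L, ..., seed = 1L) {
  I <- length(cellTypeNames(cohort))
  noiseSeeds <- deriveSeeds(seed + 1L, length(noiseFracs) * nRepeats)
  cvSeeds <- deriveSeeds(seed, nRepeats) # shared across noise levels
  res <- NULL
  k <- 0L
  for (f in noiseFracs) {
    aucs <- numeric(nRepeats)
    for (r in seq_len(nRepeats)) {
      k <- k + 1L
      co <- if (f <= 0) cohort else {
        set.seed(noiseSeeds[k])
        .corruptAnnotations(cohort, f, I)
      }
      cv <- nestedCV(co, ..., nRepeats = 1L, seed = cvSeeds[r])
      aucs[r] <- cv$summary$mean[cv$summary$metric == "auc"]
    }
    res <- rbind(res, data.frame(noise = f, meanAUC = mean(aucs),
                                 sdAUC = stats::sd(aucs),
                                 nRepeats = nRepeats))
  }
  res
}
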