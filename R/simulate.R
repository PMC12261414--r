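#' Simulate a hierarchical single-cell MIL cohort
#'
#' Generates a seeded cohort with the statistical structure the models
#' assume: per-sample cell counts drawn uniformly from a range, cell-type
#' proportions drawn from a Dirichlet (with optional per-sample dropout of
#' whole types, so absent types occur), cells assigned multinomially, and
#' Gaussian features around per-type mean profiles. Class signal enters
#' through two separately switchable channels: an expression shift (`
#' effectSize` added to the first `nSignalFeatures` features of driver-type
#' cells in positive-class samples) and a composition tilt
#' (`compositionEffect` added to the driver types' proportions in
#' positive-class samples). Optionally a stated fraction of annotations is
#' corrupted uniformly at random.
#'
#' The defaults define the package's reference signal cohort: two classes
#' of 30 samples, 5 cell types at roughly equal (~20%) expected abundance,
#' 50 features, one driver type with a shift of 2 against unit within-type
#' noise. `effectSize = 0` with `compositionEffect = 0` yields a null
#' cohort whose labels are independent of the data.
#'
#' @param S integer vector: samples per class (length = number of classes).
#' @param nCellTypes number of cell types I.
#' @param nFeatures number of features m.
#' @param cellsPerSample length-2 range; per-sample cell count is uniform
#'   on it.
#' @param typeConcentration Dirichlet concentration (scalar or length-I).
#' @param driverTypes indices of the driver cell types (carry the class
#'   signal).
#' @param effectSize mean shift added to driver-type cells of positive
#'   (class-2) samples on the signal features.
#' @param nSignalFeatures how many leading features carry the shift.
#' @param compositionEffect additive tilt of the driver types' proportion
#'   in positive samples (renormalized).
#' @param withinTypeSd,betweenTypeSd noise scales: cell-level Gaussian sd
#'   and the sd of the per-type mean profiles.
#' @param dropoutRate probability that a cell type is absent from a sample
#'   (at least one type always kept).
#' @param annotationNoise fraction of cells per sample given a uniformly
#'   random type label.
#' @param driverCellFraction fraction of driver-type cells per positive
#'   sample that carry the expression shift (1 = all; see
#'   [simulateRareDriver()]).
#' @param counts emit negative-binomial counts instead of Gaussian values
#'   (for testing the count-preprocessing pipeline); features are then
#'   `NB(mu = exp(profile), size = 10)`.
#' @param seed integer; the cohort is a deterministic function of it.
#' @return A [MILCohort]; the attribute `"groundTruth"` records the driver
#'   types, effect sizes and seed.
#' @examples
#' co <- simulateCohort(S = c(10, 10), nFeatures = 20, seed = 1)
#' co
#' @export
simulateCohort <- function(S = c(30L, 30L), nCellTypes = 5L, nFeatures = 50L,
                           cellsPerSample = c(50L, 100L),
                           typeConcentration = 5, driverTypes = 1L,
                           effectSize = 2, nSignalFeatures = 10L,
                           compositionEffect = 0, withinTypeSd = 1,
                           betweenTypeSd = 1, dropoutRate = 0.05,
                           annotationNoise = 0, driverCellFraction = 1,
                           counts = FALSE, seed = 1L) {
  I <- as.integer(nCellTypes); m <- as.integer(nFeatures)
  stopifnot(all(S >= 1L), I >= 1L, m >= 1L,
            length(cellsPerSample) == 2L, cellsPerSample[1L] >= 1L,
            dropoutRate >= 0, dropoutRate < 1,
            annotationNoise >= 0, annotationNoise <= 1,
            driverCellFraction >= 0, driverCellFraction <= 1,
            all(driverTypes >= 1L), all(driverTypes <= I))
  conc <- rep_len(typeConcentration, I)
  nsf <- min(as.integer(nSignalFeatures), m)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  mu <- matrix(rnorm(I * m, sd = betweenTypeSd), I, m) # per-type profiles
  samples <- list()
  sid <- 0L
  for (cls in seq_along(S)) {
    for (r in seq_len(S[cls])) {
      sid <- sid + 1L
      N <- sample(cellsPerSample[1L]:cellsPerSample[2L], 1L)
      p <- rgamma(I, shape = conc)
      if (dropoutRate > 0) {
        drop <- runif(I) < dropoutRate
        if (all(drop)) drop[which.max(p)] <- FALSE
        p[drop] <- 0
      }
      if (cls == 2L && compositionEffect != 0) {
        present <- p > 0
        tilt <- intersect(driverTypes, which(present))
        p[tilt] <- p[tilt] + compositionEffect * sum(p)
      }
      p <- p / sum(p)
      nPer <- drop(rmultinom(1L, N, p))
      types <- rep.int(seq_len(I), nPer)
      X <- mu[types, , drop = FALSE] +
        matrix(rnorm(length(types) * m, sd = withinTypeSd),
               length(types), m)
      if (cls == 2L && effectSize != 0 && nsf > 0L) {
        isDriver <- which(types %in% driverTypes)
        carriers <- if (driverCellFraction >= 1) isDriver
        else if (length(isDriver))
          isDriver[seq_len(ceiling(driverCellFraction * length(isDriver)))]
        else integer()
        if (length(carriers))
          X[carriers, seq_len(nsf)] <- X[carriers, seq_len(nsf)] + effectSize
      }
      if (annotationNoise > 0) {
        k <- min(length(types), ceiling(annotationNoise * length(types)))
        idx <- sample(length(types), k)
        types[idx] <- sample.int(I, k, replace = TRUE)
      }
      if (counts) X <- matrix(rnbinom(length(X), mu = exp(X), size = 10),
                              nrow(X), ncol(X))
      samples[[sid]] <- milSample(X, types, cls, sprintf("s%03d", sid))
    }
  }
  co <- milCohort(samples, cellTypeNames = paste0("type", seq_len(I)),
                  classNames = paste0("class", seq_along(S)))
  attr(co, "groundTruth") <- list(driverTypes = as.integer(driverTypes),
                                  effectSize = effectSize,
                                  compositionEffect = compositionEffect,
                                  driverCellFraction = driverCellFraction,
                                  nSignalFeatures = nsf, seed = seed)
  co
}

#' Simulate a cohort whose signal lives in a small cell subpopulation
#'
#' As [simulateCohort()], but the expression shift is applied to only a
#' fraction of the driver-type cells in each positive sample (default 10%,
#' with a stronger default shift), emulating phenotypes driven by a small
#' influential subpopulation within a cell type. `fraction = 1` reduces to
#' [simulateCohort()] exactly (same seed); `fraction = 0` yields a null
#' cohort.
#'
#' @param fraction fraction of driver-type cells carrying the shift.
#' @param effectSize mean shift for the carrier cells.
#' @param ... passed to [simulateCohort()].
#' @return A [MILCohort].
#' @export
simulateRareDriver <- function(fraction = 0.1, effectSize = 4, ...) {
  simulateCohort(driverCellFraction = fraction, effectSize = effectSize, ...)
}

#' Hard-coded micro-cohort for hand calculations
#'
#' A fixed 4-sample, 2-type, 3-feature cohort with at most 4 cells per
#' sample, including one sample with an absent cell type; used by the
#' straight-line oracle tests. The values are printed constants, not
#' generated.
#'
#' @return A [MILCohort].
#' @export
fixtureMicroCohort <- function() {
  s1 <- milSample(matrix(c( 1.0, 0.5, -0.2,
                            0.8, -0.3, 0.1,
                           -0.5, 1.2, 0.4), 3, 3, byrow = TRUE),
                  c(1L, 1L, 2L), 1L, "m1")
  s2 <- milSample(matrix(c( 0.2, -0.1, 0.7,
                            1.5, 0.3, -0.6,
                            0.0, 0.9, 0.2,
                           -1.1, 0.4, 0.8), 4, 3, byrow = TRUE),
                  c(1L, 2L, 2L, 1L), 2L, "m2")
  # s3 lacks cell type 1 entirely (exercises absent-type masking)
  s3 <- milSample(matrix(c( 0.6, -0.7, 0.3,
                            0.1, 0.2, -0.4), 2, 3, byrow = TRUE),
                  c(2L, 2L), 1L, "m3")
  s4 <- milSample(matrix(c( 2.0, 1.0, 0.5), 1, 3, byrow = TRUE),
                  c(1L), 2L, "m4")
  milCohort(list(s1, s2, s3, s4), cellTypeNames = c("typeA", "typeB"),
            classNames = c("neg", "pos"))
}
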