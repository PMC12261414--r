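#' Write a cohort to a CSV/MTX directory
#'
#' The on-disk layout is the sparse-matrix exchange convention used across
#' single-cell tools: `matrix.mtx` (cells x features, MatrixMarket),
#' `cells.tsv` (columns `sample_id`, `cell_type`), `samples.tsv` (columns
#' `sample_id`, `label`) and `features.tsv` (column `feature`). Everything
#' the package writes it can read back ([loadCohort()]).
#'
#' @param cohort a [MILCohort].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
saveCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "MILCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  X <- do.call(rbind, .cohortMatrices(cohort))
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(X), "CsparseMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  cells <- data.frame(
    sample_id = rep(sampleIds(cohort),
                    vapply(cohort@samples, function(s) nrow(s@X), integer(1))),
    cell_type = cellTypeNames(cohort)[unlist(.cohortTypes(cohort))])
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  smp <- data.frame(sample_id = sampleIds(cohort),
                    label = classNames(cohort)[sampleLabels(cohort)])
  write.table(smp, file.path(dir, "samples.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(feature = cohort@featureNames),
              file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}

#' Load a cohort from a CSV/MTX directory
#'
#' Reads the layout written by [saveCohort()]: a cells-x-features matrix
#' (`matrix.mtx`, or a dense `matrix.csv` fallback with one row per cell),
#' per-cell metadata (`cells.tsv`) and per-sample labels (`samples.tsv`).
#' Cells are grouped by sample; the cell-type vocabulary is the sorted set
#' of observed type labels and classes are encoded in sorted name order
#' (for binary tasks the lexicographically later name is the positive
#' class, unless `positiveClass` overrides it).
#'
#' @param dir directory containing the files.
#' @param sampleKey,celltypeKey column names in `cells.tsv`.
#' @param labelKey column name in `samples.tsv`.
#' @param positiveClass optional class name to force as the positive
#'   (second) class in binary tasks.
#' @return A [MILCohort].
#' @export
loadCohort <- function(dir, sampleKey = "sample_id",
                       celltypeKey = "cell_type", labelKey = "label",
                       positiveClass = NULL) {
  mtx <- file.path(dir, "matrix.mtx")
  csv <- file.path(dir, "matrix.csv")
  X <- if (file.exists(mtx)) {
    as.matrix(Matrix::readMM(mtx))
  } else if (file.exists(csv)) {
    as.matrix(utils::read.csv(csv, header = FALSE))
  } else stop("no matrix.mtx or matrix.csv in ", dir)
  dimnames(X) <- NULL
  cells <- read.delim(file.path(dir, "cells.tsv"), stringsAsFactors = FALSE)
  smp <- read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
  for (k in c(sampleKey, celltypeKey))
    if (!k %in% names(cells))
      stop("cells.tsv lacks required column '", k, "'", call. = FALSE)
  for (k in c(sampleKey, labelKey))
    if (!k %in% names(smp))
      stop("samples.tsv lacks required column '", k, "'", call. = FALSE)
  if (nrow(cells) != nrow(X))
    stop("cell metadata has ", nrow(cells), " rows but the matrix has ",
         nrow(X), " cells", call. = FALSE)
  bad <- is.na(cells[[sampleKey]]) | is.na(cells[[celltypeKey]]) |
    cells[[sampleKey]] == "" | cells[[celltypeKey]] == ""
  if (any(bad))
    stop("cells with missing sample or cell-type metadata at rows: ",
         paste(utils::head(which(bad), 10L), collapse = ", "), call. = FALSE)
  unknown <- setdiff(unique(cells[[sampleKey]]), smp[[sampleKey]])
  if (length(unknown))
    stop("cells reference unlabeled samples: ",
         paste(utils::head(unknown, 10L), collapse = ", "), call. = FALSE)

  typeNames <- sort(unique(as.character(cells[[celltypeKey]])))
  classNm <- sort(unique(as.character(smp[[labelKey]])))
  if (!is.null(positiveClass)) {
    if (!positiveClass %in% classNm)
      stop("positiveClass '", positiveClass, "' not among labels",
           call. = FALSE)
    classNm <- c(setdiff(classNm, positiveClass), positiveClass)
  }
  labelOf <- setNames(match(as.character(smp[[labelKey]]), classNm),
                      smp[[sampleKey]])
  feat <- file.path(dir, "features.tsv")
  featureNames <- if (file.exists(feat)) read.delim(feat)$feature
                  else paste0("f", seq_len(ncol(X)))
  sampleOrder <- unique(cells[[sampleKey]])
  samples <- lapply(sampleOrder, function(sidv) {
    idx <- which(cells[[sampleKey]] == sidv)
    milSample(X[idx, , drop = FALSE],
              match(cells[[celltypeKey]][idx], typeNames),
              labelOf[[sidv]], sidv)
  })
  milCohort(samples, cellTypeNames = typeNames, classNames = classNm,
            featureNames = as.character(featureNames))
}

#' Build a cohort from a SingleCellExperiment
#'
#' Converts an in-memory `SingleCellExperiment` (cells as columns) whose
#' `colData` carries a sample-id column and a cell-type column into a
#' [MILCohort]. Sample labels come from a named vector or from a
#' sample-level column of `colData` (constant within sample).
#'
#' @param sce a `SingleCellExperiment`.
#' @param labels named character/factor vector of per-sample labels (names
#'   = sample ids), or the name of a `colData` column.
#' @param sampleKey,celltypeKey `colData` column names.
#' @param assayName which assay to use (default: the first).
#' @param positiveClass optional positive-class override (see
#'   [loadCohort()]).
#' @return A [MILCohort].
#' @export
cohortFromSCE <- function(sce, labels, sampleKey = "sample_id",
                          celltypeKey = "cell_type", assayName = NULL,
                          positiveClass = NULL) {
  if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
    stop("cohortFromSCE needs the SummarizedExperiment package")
  cd <- SummarizedExperiment::colData(sce)
  for (k in c(sampleKey, celltypeKey))
    if (!k %in% colnames(cd))
      stop("colData lacks required column '", k, "'", call. = FALSE)
  A <- if (is.null(assayName)) SummarizedExperiment::assay(sce, 1L)
       else SummarizedExperiment::assay(sce, assayName)
  sampleVec <- as.character(cd[[sampleKey]])
  typeVec <- as.character(cd[[celltypeKey]])
  if (is.character(labels) && length(labels) == 1L && labels %in% colnames(cd)) {
    lab <- tapply(as.character(cd[[labels]]), sampleVec, function(v) v[1L])
    labels <- setNames(as.character(lab), names(lab))
  }
  missing <- setdiff(unique(sampleVec), names(labels))
  if (length(missing))
    stop("no label for samples: ", paste(head(missing, 10L), collapse = ", "),
         call. = FALSE)
  typeNames <- sort(unique(typeVec))
  classNm <- sort(unique(as.character(labels)))
  if (!is.null(positiveClass))
    classNm <- c(setdiff(classNm, positiveClass), positiveClass)
  X <- t(as.matrix(A)) # cells x features
  samples <- lapply(unique(sampleVec), function(sidv) {
    idx <- which(sampleVec == sidv)
    milSample(X[idx, , drop = FALSE], match(typeVec[idx], typeNames),
              match(as.character(labels[[sidv]]), classNm), sidv)
  })
  fn <- rownames(sce)
  milCohort(samples, cellTypeNames = typeNames, classNames = classNm,
            featureNames = if (is.null(fn)) paste0("f", seq_len(ncol(X)))
                           else fn)
}

#' Count preprocessing: library-size normalization and log transform
#'
#' Scales every cell's counts to a total of `targetSum` (default 1e4) and
#' applies `log1p`. Optionally first removes, cohort-wide, genes with
#' nonzero expression in fewer than `minCells` cells. All-zero cells are
#' left unchanged with a warning; negative entries are an error.
#'
#' @param cohort a [MILCohort] of non-negative counts.
#' @param targetSum per-cell total after scaling.
#' @param filterGenes drop rarely expressed genes first?
#' @param minCells threshold for the gene filter (a gene is kept when it is
#'   nonzero in at least this many cells across the cohort).
#' @return The transformed [MILCohort] (feature space possibly reduced).
#' @export
preprocessCounts <- function(cohort, targetSum = 1e4, filterGenes = TRUE,
                             minCells = 5L) {
  stopifnot(is(cohort, "MILCohort"))
  mats <- .cohortMatrices(cohort)
  if (any(vapply(mats, function(X) any(X < 0), logical(1))))
    stop("negative entries: preprocessCounts expects raw counts",
         call. = FALSE)
  if (filterGenes) {
    nnz <- Reduce(`+`, lapply(mats, function(X) colSums(X > 0)))
    keep <- nnz >= minCells
    if (!any(keep)) stop("gene filter removed every feature", call. = FALSE)
    cohort@samples <- lapply(cohort@samples, function(s)
      initialize(s, X = s@X[, keep, drop = FALSE]))
    cohort@featureNames <- cohort@featureNames[keep]
  }
  zeroCells <- 0L
  cohort@samples <- lapply(cohort@samples, function(s) {
    tot <- rowSums(s@X)
    zero <- tot == 0
    zeroCells <<- zeroCells + sum(zero)
    sc <- ifelse(zero, 0, targetSum / tot)
    initialize(s, X = log1p(s@X * sc))
  })
  if (zeroCells > 0L)
    warning(zeroCells, " all-zero cell(s) left unchanged")
  cohort
}
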