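#' Construct a MIL sample (bag)
#'
#' @param X numeric matrix of cells x features.
#' @param cellType integer vector of 1-based cell-type ids, one per cell.
#' @param label integer 1-based class label of the sample.
#' @param sampleId character identifier.
#' @return A [MILSample].
#' @examples
#' s <- milSample(matrix(rnorm(6), 2, 3), c(1L, 2L), 1L, "s1")
#' @export
milSample <- function(X, cellType, label, sampleId) {
  new("MILSample", X = as.matrix(X), cellType = as.integer(cellType),
      label = as.integer(label), sampleId = as.character(sampleId))
}

#' Construct a MIL cohort
#'
#' @param samples list of [MILSample] sharing one feature space.
#' @param cellTypeNames character vocabulary of cell types.
#' @param classNames character vector of class names; for binary tasks the
#'   second entry is treated as the positive class.
#' @param featureNames optional character vector of feature names; defaults
#'   to `f1..fm`.
#' @return A [MILCohort].
#' @export
milCohort <- function(samples, cellTypeNames, classNames, featureNames = NULL) {
  if (is.null(featureNames)) {
    m <- ncol(samples[[1L]]@X)
    featureNames <- paste0("f", seq_len(m))
  }
  co <- new("MILCohort", samples = samples,
            cellTypeNames = as.character(cellTypeNames),
            classNames = as.character(classNames),
            featureNames = as.character(featureNames))
  labs <- sampleLabels(co)
  if (!all(seq_along(co@classNames) %in% labs))
    stop("every class must be present in at least one sample ",
         "(fold subsets of an existing cohort are exempt)", call. = FALSE)
  co
}

#' Cohort accessors
#'
#' @param x a [MILCohort].
#' @return `nSamples()` the number of bags; `cellTypeNames()` /
#'   `classNames()` the vocabularies; `sampleLabels()` the integer class
#'   labels; `sampleIds()` the sample identifiers.
#' @name MILCohort-accessors
NULL

#' @rdname MILCohort-accessors
#' @export
setMethod("nSamples", "MILCohort", function(x) length(x@samples))

#' @rdname MILCohort-accessors
#' @export
setMethod("cellTypeNames", "MILCohort", function(x) x@cellTypeNames)

#' @rdname MILCohort-accessors
#' @export
setMethod("cellTypeNames", "MILModel", function(x) x@cellTypeNames)

#' @rdname MILCohort-accessors
#' @export
setMethod("classNames", "MILCohort", function(x) x@classNames)

#' @rdname MILCohort-accessors
#' @export
setMethod("classNames", "MILModel", function(x) x@classNames)

#' @rdname MILCohort-accessors
#' @export
setMethod("sampleLabels", "MILCohort", function(x)
  vapply(x@samples, function(s) s@label, integer(1)))

#' @rdname MILCohort-accessors
#' @export
setMethod("sampleIds", "MILCohort", function(x)
  vapply(x@samples, function(s) s@sampleId, character(1)))

#' Subset a cohort by sample index
#'
#' @param x a [MILCohort].
#' @param i integer or logical index over samples.
#' @param j,drop,... ignored.
#' @return A [MILCohort] with the selected bags (vocabularies unchanged).
#' @export
setMethod("[", "MILCohort", function(x, i, j, ..., drop = FALSE) {
  initialize(x, samples = x@samples[i])
})

setMethod("show", "MILSample", function(object) {
  cat("MILSample", object@sampleId, ":", nrow(object@X), "cells x",
      ncol(object@X), "features,", length(unique(object@cellType)),
      "cell types, label", object@label, "\n")
})

setMethod("show", "MILCohort", function(object) {
  labs <- sampleLabels(object)
  N <- vapply(object@samples, function(s) nrow(s@X), integer(1))
  cat("MILCohort:", length(object@samples), "samples,",
      length(object@cellTypeNames), "cell types,",
      length(object@featureNames), "features\n")
  cat("  classes:",
      paste(sprintf("%s (%d)", object@classNames,
                    tabulate(labs, length(object@classNames))),
            collapse = ", "), "\n")
  cat("  cells per sample:", min(N), "-", max(N),
      sprintf("(median %.0f)", stats::median(N)), "\n")
})

# relabel a cohort (used by the permutation test); labels recycled by index
.withLabels <- function(cohort, labels) {
  stopifnot(length(labels) == length(cohort@samples))
  cohort@samples <- mapply(function(s, l) { s@label <- as.integer(l); s },
                           cohort@samples, labels, SIMPLIFY = FALSE)
  cohort
}
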