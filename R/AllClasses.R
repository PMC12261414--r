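#' Bag of annotated cells from one sample
#'
#' A `MILSample` is one multiple-instance-learning bag: the cells of a single
#' patient sample. It holds the cells-by-features expression (or embedding)
#' matrix, an integer cell-type id per cell, and the sample-level class label.
#' Cell-type ids index into the cohort-wide vocabulary; a sample need not
#' contain every cell type.
#'
#' @slot X numeric matrix, cells x features; must be finite.
#' @slot cellType integer vector, one 1-based cell-type id per cell.
#' @slot label integer scalar, 1-based class id.
#' @slot sampleId character scalar.
#'
#' @seealso [MILCohort], [simulateCohort()]
#' @export
setClass("MILSample",
  representation(X = "matrix", cellType = "integer", label = "integer",
                 sampleId = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@X) < 1L)
      msg <- c(msg, "sample must contain at least one cell")
    if (!all(is.finite(object@X)))
      msg <- c(msg, "X contains non-finite entries")
    if (length(object@cellType) != nrow(object@X))
      msg <- c(msg, "cellType length must equal nrow(X)")
    if (any(object@cellType < 1L))
      msg <- c(msg, "cellType ids must be >= 1")
    if (length(object@label) != 1L || is.na(object@label) || object@label < 1L)
      msg <- c(msg, "label must be a single positive integer")
    if (length(object@sampleId) != 1L)
      msg <- c(msg, "sampleId must be a single string")
    if (length(msg)) msg else TRUE
  })

#' Cohort of annotated single-cell samples
#'
#' A `MILCohort` collects [MILSample] bags that share a cell-type vocabulary,
#' a class set and a feature space. It is the input to model fitting,
#' cross-validation and the importance-score machinery.
#'
#' @slot samples list of [MILSample].
#' @slot cellTypeNames character vector naming the I cell types; every
#'   `cellType` id in every sample indexes into it.
#' @slot classNames character vector naming the C classes. For binary tasks
#'   the second entry is the positive class.
#' @slot featureNames character vector of length m (feature space shared by
#'   all samples).
#'
#' @seealso [simulateCohort()], [loadCohort()], [cohortFromSCE()]
#' @export
setClass("MILCohort",
  representation(samples = "list", cellTypeNames = "character",
                 classNames = "character", featureNames = "character"),
  validity = function(object) {
    msg <- character()
    if (!length(object@samples))
      msg <- c(msg, "cohort has no samples")
    if (!all(vapply(object@samples, is, logical(1), "MILSample")))
      msg <- c(msg, "samples must all be MILSample objects")
    I <- length(object@cellTypeNames)
    C <- length(object@classNames)
    m <- length(object@featureNames)
    for (s in object@samples) {
      if (ncol(s@X) != m) {
        msg <- c(msg, "all samples must share the cohort feature space")
        break
      }
      if (any(s@cellType > I)) {
        msg <- c(msg, "cellType id outside the cohort vocabulary")
        break
      }
      if (s@label > C) {
        msg <- c(msg, "class label outside the cohort class set")
        break
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Hierarchical attention MIL model
#'
#' Configuration plus all trainable parameters of one model. `mode` selects
#' the aggregation architecture:
#' \describe{
#'   \item{`"CTA"`}{mean pooling of cells within a type, attention over types.}
#'   \item{`"HA"`}{attention over cells within a type, then over types.}
#'   \item{`"meanPool"`}{ablation: plain average over all cells (pseudo-bulk).}
#'   \item{`"cellAtt"`}{ablation: one flat softmax attention over all cells,
#'     ignoring types.}
#' }
#'
#' Parameters (`params`) are stored as a named list of matrices: encoder
#' weights `Wx1`/`bx1` (and `Wx2`/`bx2` for two hidden layers), cell-attention
#' `w`/`b`, type-attention `v`/`bprime`, and either a binary head
#' `wbar`/`bbar` (sigmoid) or a multi-class head `W`/`bhead` (softmax).
#'
#' @slot mode character; one of `"CTA"`, `"HA"`, `"meanPool"`, `"cellAtt"`.
#' @slot nHiddenLayers integer, 1 or 2.
#' @slot hiddenDim integer, width d of the cell representation.
#' @slot inputDim integer, number of input features m.
#' @slot nClasses integer C.
#' @slot nonlinearity character, `"relu"` (default) or `"tanh"`.
#' @slot binaryHead logical; sigmoid head (only allowed when C = 2).
#' @slot params named list of parameter matrices (see Details).
#' @slot cellTypeNames,classNames vocabularies copied from the training cohort.
#' @slot seed integer used to initialize the parameters.
#'
#' @seealso [milModel()], [fitModel()], [predictProba()]
#' @export
setClass("MILModel",
  representation(mode = "character", nHiddenLayers = "integer",
                 hiddenDim = "integer", inputDim = "integer",
                 nClasses = "integer", nonlinearity = "character",
                 binaryHead = "logical", params = "list",
                 cellTypeNames = "character", classNames = "character",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@mode %in% c("CTA", "HA", "meanPool", "cellAtt"))
      msg <- c(msg, "mode must be one of CTA, HA, meanPool, cellAtt")
    if (!object@nHiddenLayers %in% 1:2)
      msg <- c(msg, "nHiddenLayers must be 1 or 2")
    if (object@hiddenDim < 1L) msg <- c(msg, "hiddenDim must be >= 1")
    if (!object@nonlinearity %in% c("relu", "tanh"))
      msg <- c(msg, "nonlinearity must be relu or tanh")
    if (object@binaryHead && object@nClasses != 2L)
      msg <- c(msg, "binary head requires exactly 2 classes")
    if (!all(vapply(object@params, function(p) all(is.finite(p)), logical(1))))
      msg <- c(msg, "parameters contain non-finite values")
    if (length(msg)) msg else TRUE
  })

#' Cell-type importance report
#'
#' Result of [permutationTest()]: the observed per-cell-type importance score
#' kappa (class contrast of mean type-level logit contributions), its
#' label-permutation null draws, empirical p-values (add-one estimator),
#' multiplicity-adjusted p-values, and the resulting criticality calls.
#'
#' @slot kappa named numeric, observed importance score per cell type.
#' @slot nullKappas numeric matrix, nPermutations x nTypes of null draws.
#' @slot pRaw,pAdj named numeric, raw and adjusted p-values in (0, 1].
#' @slot critical named logical; `pAdj <= alpha`.
#' @slot nPermutations integer.
#' @slot correctionMethod character (`"BH"`, `"holm"`, `"bonferroni"`).
#' @slot alpha numeric significance level.
#' @slot sided character, `"two.sided"` (default) or `"greater"`.
#' @slot seed integer.
#' @slot targetClass character; the class whose logit component was
#'   contrasted (for multi-class one-vs-rest scores; `NA` for the plain
#'   binary score).
#'
#' @seealso [rankCellTypes()], [importanceScores()]
#' @export
setClass("ImportanceReport",
  representation(kappa = "numeric", nullKappas = "matrix", pRaw = "numeric",
                 pAdj = "numeric", critical = "logical",
                 nPermutations = "integer", correctionMethod = "character",
                 alpha = "numeric", sided = "character", seed = "integer",
                 targetClass = "character"),
  validity = function(object) {
    msg <- character()
    if (any(object@pRaw <= 0 | object@pRaw > 1))
      msg <- c(msg, "raw p-values must lie in (0, 1]")
    if (any(object@pAdj + 1e-12 < object@pRaw))
      msg <- c(msg, "adjusted p-values must be >= raw p-values")
    if (!identical(unname(object@critical),
                   unname(object@pAdj <= object@alpha)))
      msg <- c(msg, "critical calls must equal pAdj <= alpha")
    if (length(msg)) msg else TRUE
  })
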