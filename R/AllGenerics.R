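#' @rdname MILCohort-accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname MILCohort-accessors
#' @export
setGeneric("cellTypeNames", function(x) standardGeneric("cellTypeNames"))

#' @rdname MILCohort-accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' @rdname MILCohort-accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname MILCohort-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname fitModel
#' @export
setGeneric("fitModel", function(object, cohort, ...) standardGeneric("fitModel"))

#' @rdname predictProba
#' @export
setGeneric("predictProba", function(object, newdata, ...)
  standardGeneric("predictProba"))

#' @rdname sampleRepresentation
#' @export
setGeneric("sampleRepresentation", function(object, sample, ...)
  standardGeneric("sampleRepresentation"))

#' @rdname decompose
#' @export
setGeneric("decompose", function(object, sample, ...)
  standardGeneric("decompose"))

#' @rdname rankCellTypes
#' @export
setGeneric("rankCellTypes", function(report) standardGeneric("rankCellTypes"))
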