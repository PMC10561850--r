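#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("classSet", function(x) standardGeneric("classSet"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("classCodes", function(x) standardGeneric("classCodes"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' @rdname ExpressionDataset-accessors
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))

#' @rdname planeProjection
#' @export
setGeneric("planeProjection", function(samples, plane)
  standardGeneric("planeProjection"))
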