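#' Construct an ExpressionDataset
#'
#' Build an [ExpressionDataset-class] from a samples-by-probes value matrix
#' (the orientation of a CuMiDa CSV: one row per sample) and a class label
#' per sample.  The class set is recorded in first-appearance order of the
#' labels and frozen, so class codes stay stable when the object is
#' subset later (e.g. by a train/test split that happens to reorder first
#' appearances).
#'
#' @param values numeric matrix, samples x probes.
#' @param labels class label per sample (character or factor; coerced to
#'   character).
#' @param sampleIds,probeIds identifiers; default to the dimnames of
#'   \code{values} or are synthesized.
#' @param classSet optional explicit ordered class set; defaults to
#'   first-appearance order of \code{labels}.
#' @return An [ExpressionDataset-class].
#' @examples
#' x <- ExpressionDataset(matrix(rnorm(8), 2, 4), labels = c("a", "b"))
#' classSet(x)
#' @export
ExpressionDataset <- function(values, labels, sampleIds = NULL,
                              probeIds = NULL, classSet = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  n <- nrow(values); p <- ncol(values)
  labels <- as.character(labels)
  if (length(labels) != n)
    stop("need one label per sample (", n, " samples, ",
         length(labels), " labels)")
  if (any(is.na(labels) | labels == ""))
    stop("samples with unknown/empty class label are rejected")
  if (is.null(sampleIds)) sampleIds <- rownames(values)
  if (is.null(sampleIds)) sampleIds <- sprintf("sample_%d", seq_len(n))
  if (is.null(probeIds)) probeIds <- colnames(values)
  if (is.null(probeIds)) probeIds <- sprintf("probe_%d", seq_len(p))
  if (anyDuplicated(probeIds)) stop("probe ids must be unique")
  if (is.null(classSet)) classSet <- unique(labels)
  dimnames(values) <- NULL
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(exprs = t(values)),
    colData = S4Vectors::DataFrame(type = labels, row.names = sampleIds))
  rownames(se) <- as.character(probeIds)
  S4Vectors::metadata(se)$classSet <- as.character(classSet)
  new("ExpressionDataset", se)
}

#' Accessors for ExpressionDataset
#'
#' \code{expressionMatrix} returns the values in analysis orientation
#' (samples x probes); \code{classCodes} returns integer codes \code{1..c}
#' positioning each sample's label in the frozen class set;
#' \code{classCounts} tabulates samples per class in class-set order.
#'
#' @param x an [ExpressionDataset-class].
#' @name ExpressionDataset-accessors
#' @aliases probeIds sampleIds classLabels classSet classCodes classCounts
#'   expressionMatrix
NULL

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("probeIds", "ExpressionDataset", function(x) rownames(x))

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("sampleIds", "ExpressionDataset", function(x) colnames(x))

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("classLabels", "ExpressionDataset",
  function(x) as.character(SummarizedExperiment::colData(x)$type))

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("classSet", "ExpressionDataset",
  function(x) S4Vectors::metadata(x)$classSet)

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("classCodes", "ExpressionDataset",
  function(x) match(classLabels(x), classSet(x)))

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("classCounts", "ExpressionDataset", function(x) {
  cs <- classSet(x)
  stats::setNames(tabulate(classCodes(x), nbins = length(cs)), cs)
})

#' @rdname ExpressionDataset-accessors
#' @export
setMethod("expressionMatrix", "ExpressionDataset", function(x) {
  m <- t(SummarizedExperiment::assay(x, "exprs"))
  dimnames(m) <- list(sampleIds(x), probeIds(x))
  m
})

setMethod("show", "ExpressionDataset", function(object) {
  cc <- classCounts(object)
  cat("ExpressionDataset:", ncol(object), "samples x", nrow(object),
      "probes\n")
  cat("classes (", length(cc), "): ",
      paste(sprintf("%s=%d", names(cc), cc), collapse = ", "), "\n", sep = "")
})

#' Replace the expression values of a dataset
#'
#' Returns a copy of \code{x} whose assay holds \code{values} (samples x
#' probes, same shape as \code{expressionMatrix(x)}); all metadata is kept.
#' Used to carry normalized values through the pipeline.
#'
#' @param x an [ExpressionDataset-class].
#' @param values numeric matrix, samples x probes.
#' @return An [ExpressionDataset-class].
#' @export
setExpressionValues <- function(x, values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(x) || ncol(values) != nrow(x))
    stop("replacement values have the wrong shape")
  dimnames(values) <- NULL
  SummarizedExperiment::assay(x, "exprs", withDimnames = FALSE) <- t(values)
  validObject(x)
  x
}

#' Subset a dataset to selected samples
#'
#' @param x an [ExpressionDataset-class].
#' @param idx sample indices.
#' @return An [ExpressionDataset-class] with the same frozen class set.
#' @keywords internal
.subsetSamples <- function(x, idx) x[, idx]
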