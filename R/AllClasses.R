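#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors metadata DataFrame SimpleList
NULL

#' ExpressionDataset: labelled expression matrix
#'
#' An \code{ExpressionDataset} holds a samples-by-probes expression table
#' together with sample identifiers, probe-set identifiers and a class label
#' per sample.  It extends
#' \link[SummarizedExperiment]{SummarizedExperiment}; the single assay
#' \code{"exprs"} is stored probes x samples in the Bioconductor orientation,
#' class labels live in \code{colData(x)$type}, and the ordered class set
#' (first-appearance order, frozen at construction so that integer class
#' codes stay stable under subsetting) is kept in \code{metadata(x)$classSet}.
#'
#' @slot .Data see \link[SummarizedExperiment]{SummarizedExperiment}.
#' @seealso [ExpressionDataset()] for the user constructor,
#'   [readCumidaCsv()] for loading CuMiDa-style CSV files.
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

.validExpressionDataset <- function(object) {
  msg <- NULL
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(m)) msg <- c(msg, "assay 'exprs' must be numeric")
    if (anyNA(m)) msg <- c(msg, "expression values contain missing entries")
  }
  if (!"type" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData column 'type' (class label) is required")
  cs <- S4Vectors::metadata(object)$classSet
  if (is.null(cs)) msg <- c(msg, "metadata 'classSet' is required")
  else {
    lab <- as.character(SummarizedExperiment::colData(object)$type)
    if (length(lab) && !all(lab %in% cs))
      msg <- c(msg, "labels outside the recorded class set")
    if (anyDuplicated(cs)) msg <- c(msg, "classSet has duplicates")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids are not unique")
  if (is.null(msg)) TRUE else msg
}
setValidity("ExpressionDataset", .validExpressionDataset)

#' SplitResult: a seeded stratified train/test partition
#'
#' @slot train,test [ExpressionDataset-class] parts of the partition.
#' @slot perClassCounts data.frame with columns \code{class}, \code{nTrain},
#'   \code{nTest}.
#' @slot seed integer seed that produced the split.
#' @exportClass SplitResult
setClass("SplitResult",
  representation(train = "ExpressionDataset", test = "ExpressionDataset",
                 perClassCounts = "data.frame", seed = "integer"))

#' ScalingParams: affine min-max normalization parameters
#'
#' Per-feature minima and maxima plus the affine constants \eqn{\alpha} and
#' \eqn{\beta} of the map \eqn{z = \alpha (y - y_{min})/(y_{max} - y_{min}) -
#' \beta}.  Features with \eqn{y_{max} = y_{min}} are flagged degenerate and
#' transform to the range midpoint \eqn{\alpha/2 - \beta}.
#'
#' @slot alpha,beta numeric constants with \code{alpha > beta >= 0}.
#' @slot featureMin,featureMax named numeric vectors, one entry per probe.
#' @slot degenerate logical vector flagging constant features.
#' @slot fittedOn \code{"train"} or \code{"all"}.
#' @exportClass ScalingParams
setClass("ScalingParams",
  representation(alpha = "numeric", beta = "numeric",
                 featureMin = "numeric", featureMax = "numeric",
                 degenerate = "logical", fittedOn = "character"))

setValidity("ScalingParams", function(object) {
  msg <- NULL
  if (object@alpha <= object@beta) msg <- c(msg, "alpha must exceed beta")
  if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
  if (length(object@featureMin) != length(object@featureMax))
    msg <- c(msg, "featureMin/featureMax length mismatch")
  if (any(object@featureMax < object@featureMin))
    msg <- c(msg, "featureMax below featureMin")
  if (is.null(msg)) TRUE else msg
})

#' ClassCenteredMatrix: per-class mean-removed expression values
#'
#' Rows are grouped into contiguous per-class blocks (class-code order);
#' within each block every column has mean zero.
#'
#' @slot centered numeric matrix, rows grouped by class.
#' @slot classBlocks named list mapping class label to its row indices in
#'   \code{centered}.
#' @slot classMeans numeric matrix, one row per class, of the removed means.
#' @slot rowIndex integer vector: row r of \code{centered} came from row
#'   \code{rowIndex[r]} of the input matrix.
#' @exportClass ClassCenteredMatrix
setClass("ClassCenteredMatrix",
  representation(centered = "matrix", classBlocks = "list",
                 classMeans = "matrix", rowIndex = "integer"))

#' FeatureScores: the per-feature selection measure
#'
#' @slot scores numeric vector, one nonnegative score per feature.
#' @slot mode \code{"margin"} (largest one-dimensional inter-class gap on
#'   normalized values) or \code{"literal"} (floor-at-zero column minimum of
#'   the class-centered matrix).
#' @slot ranking integer permutation of the features: descending score,
#'   ties by ascending index.
#' @exportClass FeatureScores
setClass("FeatureScores",
  representation(scores = "numeric", mode = "character",
                 ranking = "integer"))

#' SelectedFeatures: the chosen top-k feature set
#'
#' @slot k number of features retained.
#' @slot indices integer feature indices (1-based file order), in ranking
#'   order.
#' @slot probeIds matching probe-set identifiers.
#' @exportClass SelectedFeatures
setClass("SelectedFeatures",
  representation(k = "integer", indices = "integer", probeIds = "character"))

#' LPProblem: the pairwise L1-slack separability linear program
#'
#' Free-variable form of the program: decision vector \eqn{(w, b, y, z)} with
#' \eqn{w \in R^k}, bias \eqn{b}, and nonnegative slacks \eqn{y} (one per
#' positive-class sample) and \eqn{z} (one per negative-class sample);
#' constraint rows \eqn{w \cdot d_u - b + y_u \ge 1} and
#' \eqn{-w \cdot d_v + b + z_v \ge 1}; objective
#' \eqn{\min (1/n_i) \sum y_u + (1/n_j) \sum z_v}.
#'
#' @slot constraints numeric matrix, \code{(nPos+nNeg)} rows by
#'   \code{(k+1+nPos+nNeg)} columns, variables ordered \code{(w, b, y, z)}.
#' @slot rhs right-hand sides (all ones).
#' @slot objective objective coefficients (zero on \code{w} and \code{b}).
#' @slot weightDim,nPos,nNeg problem dimensions.
#' @exportClass LPProblem
setClass("LPProblem",
  representation(constraints = "matrix", rhs = "numeric",
                 objective = "numeric", weightDim = "integer",
                 nPos = "integer", nNeg = "integer"))

#' SeparatingPlane: a fitted pairwise hyperplane
#'
#' Orientation: the first class of \code{pair} is the positive side
#' (\eqn{w \cdot x - b \ge 1} targeted), the second the negative side.  The
#' optimal objective is zero (up to tolerance) exactly when the two point
#' sets are linearly separable.
#'
#' @slot pair integer vector of length 2: class codes (positive, negative).
#' @slot pairLabels matching class labels.
#' @slot weights numeric weight vector of length k.
#' @slot bias the LP bias b.
#' @slot objectiveValue optimal value of the slack objective (>= 0).
#' @slot separable logical: objective within tolerance of zero.
#' @slot solverStatus solver status tag.
#' @exportClass SeparatingPlane
setClass("SeparatingPlane",
  representation(pair = "integer", pairLabels = "character",
                 weights = "numeric", bias = "numeric",
                 objectiveValue = "numeric", separable = "logical",
                 solverStatus = "character"))

#' CalibratedPlane: a plane plus a re-learned decision threshold
#'
#' The threshold maximizes the number of correct binary decisions of the
#' projection \eqn{w \cdot x} on the calibration samples; the LP bias is not
#' used at decision time (the threshold plays the bias role).
#'
#' @slot plane [SeparatingPlane-class].
#' @slot threshold scalar decision threshold on the projection scale.
#' @slot calibrationAccuracy fraction of calibration samples decided
#'   correctly at the threshold.
#' @exportClass CalibratedPlane
setClass("CalibratedPlane",
  representation(plane = "SeparatingPlane", threshold = "numeric",
                 calibrationAccuracy = "numeric"))
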