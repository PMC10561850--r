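#' Fit affine min-max scaling parameters
#'
#' Records, per feature, the minimum and maximum over the supplied samples
#' for the affine normalization
#' \deqn{z = \alpha \frac{y - y_{min}}{y_{max} - y_{min}} - \beta,}
#' with constants \eqn{\alpha > \beta \ge 0}.  With the defaults
#' \eqn{\alpha = 2, \beta = 1} the fitted samples map into \eqn{[-1, 1]}.
#' Constant features are flagged degenerate; they transform to the range
#' midpoint \eqn{\alpha/2 - \beta} and are excluded from feature selection.
#'
#' @param train an [ExpressionDataset-class] (typically the training part).
#' @param alpha,beta the affine constants; \code{alpha > beta} required.
#' @param fittedOn tag recording the fitting population (\code{"train"} or
#'   \code{"all"}); informational.
#' @return A [ScalingParams-class].
#' @export
fitMinmax <- function(train, alpha = 2, beta = 1, fittedOn = "train") {
  if (alpha <= beta) stop("alpha must exceed beta")
  m <- expressionMatrix(train)
  if (nrow(m) == 0L) stop("cannot fit scaling on an empty dataset")
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  new("ScalingParams", alpha = alpha, beta = beta,
      featureMin = lo, featureMax = hi,
      degenerate = hi == lo, fittedOn = fittedOn)
}

#' Apply min-max normalization
#'
#' Applies the affine map recorded in \code{params} to every feature.
#' Test values outside the fitted range are allowed and map outside
#' \eqn{[-\beta, \alpha - \beta]}.
#'
#' @param data an [ExpressionDataset-class] or samples-x-probes matrix with
#'   the same probe set and order as the fit.
#' @param params a [ScalingParams-class].
#' @return Numeric matrix, samples x probes, of normalized values.
#' @export
transformMinmax <- function(data, params) {
  m <- if (is(data, "ExpressionDataset")) expressionMatrix(data)
       else as.matrix(data)
  p <- length(params@featureMin)
  if (ncol(m) != p) stop("probe mismatch: data has ", ncol(m),
                         " features, params ", p)
  if (is(data, "ExpressionDataset") &&
      !is.null(names(params@featureMin)) &&
      !identical(unname(probeIds(data)), unname(names(params@featureMin))))
    stop("probe mismatch: ids/order differ from the fit")
  rng <- params@featureMax - params@featureMin
  z <- sweep(m, 2, params@featureMin)
  z <- sweep(z, 2, ifelse(params@degenerate, 1, rng), "/")
  z <- params@alpha * z - params@beta
  mid <- params@alpha / 2 - params@beta
  if (any(params@degenerate)) z[, params@degenerate] <- mid
  z
}

#' Per-class mean centering
#'
#' Splits the normalized matrix by class, removes each class's mean vector,
#' and concatenates the centered blocks in class-code order.  Centering is a
#' projection: applying it twice equals applying it once.
#'
#' @param normalized numeric matrix, samples x features.
#' @param codes integer class code per row (1..c).
#' @param classLabels optional labels naming the blocks.
#' @return A [ClassCenteredMatrix-class].
#' @export
centerByClass <- function(normalized, codes, classLabels = NULL) {
  normalized <- as.matrix(normalized)
  codes <- as.integer(codes)
  if (length(codes) != nrow(normalized))
    stop("need one class code per row")
  present <- sort(unique(codes))
  if (is.null(classLabels)) classLabels <- as.character(present)
  else classLabels <- classLabels[present]
  blocks <- list(); means <- NULL; rowIndex <- integer(0)
  centered <- NULL; at <- 0L
  for (k in seq_along(present)) {
    idx <- which(codes == present[k])
    if (!length(idx)) stop("empty class block")
    blk <- normalized[idx, , drop = FALSE]
    mu <- colMeans(blk)
    centered <- rbind(centered, sweep(blk, 2, mu))
    means <- rbind(means, mu)
    blocks[[classLabels[k]]] <- at + seq_along(idx)
    at <- at + length(idx)
    rowIndex <- c(rowIndex, idx)
  }
  rownames(means) <- classLabels
  new("ClassCenteredMatrix", centered = unname(centered),
      classBlocks = blocks, classMeans = means, rowIndex = rowIndex)
}
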