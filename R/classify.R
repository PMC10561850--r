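#' Project samples onto a plane's weight vector
#'
#' Returns \eqn{w \cdot x} per sample.  The LP bias is deliberately not
#' subtracted: the calibrated threshold plays the bias role at decision
#' time.
#'
#' @param samples a samples-x-k matrix or an [ExpressionDataset-class]
#'   restricted to the plane's features.
#' @param plane a [SeparatingPlane-class] or [CalibratedPlane-class].
#' @return Numeric projection vector, one value per sample.
#' @export
#' @rdname planeProjection
setMethod("planeProjection", signature("matrix", "SeparatingPlane"),
  function(samples, plane) {
    if (ncol(samples) != length(plane@weights))
      stop("dimension mismatch: ", ncol(samples), " features vs ",
           length(plane@weights), " weights")
    as.vector(samples %*% plane@weights)
  })

#' @rdname planeProjection
setMethod("planeProjection", signature("ExpressionDataset", "SeparatingPlane"),
  function(samples, plane)
    planeProjection(expressionMatrix(samples), plane))

#' @rdname planeProjection
setMethod("planeProjection", signature("ANY", "CalibratedPlane"),
  function(samples, plane) planeProjection(samples, plane@plane))

#' Optimal decision threshold for a projection
#'
#' Finds the threshold \eqn{Q^*} maximizing the number of correct binary
#' decisions, where a sample is called positive when its projection exceeds
#' the threshold.  Candidate cuts are the \eqn{m + 1} positions around the
#' \eqn{m} distinct projection values; among accuracy maximizers the
#' midpoint of the widest gap between adjacent distinct values wins, ties on
#' gap width going to the smallest threshold.  The two outer cuts sit one
#' unit beyond the extremes.  With only one label present the threshold is
#' placed so that every sample is decided correctly.
#'
#' @param projections numeric vector.
#' @param positive logical vector: \code{TRUE} for positive-class samples.
#' @return list with \code{threshold} and \code{accuracy} (fraction
#'   correct).
#' @export
optimalThreshold <- function(projections, positive) {
  stopifnot(length(projections) == length(positive))
  positive <- as.logical(positive)
  n <- length(projections)
  if (n == 0) stop("no calibration samples")
  v <- sort(unique(projections))
  m <- length(v)
  cuts <- c(v[1] - 1, if (m > 1) (v[-m] + v[-1]) / 2, v[m] + 1)
  gaps <- c(2, if (m > 1) diff(v), 2)
  best <- NULL
  for (t in seq_along(cuts)) {
    q <- cuts[t]
    acc <- sum(positive & projections > q) + sum(!positive & projections <= q)
    if (is.null(best) || acc > best$acc ||
        (acc == best$acc && (gaps[t] > best$gap ||
                             (gaps[t] == best$gap && q < best$q)))) {
      best <- list(acc = acc, gap = gaps[t], q = q)
    }
  }
  list(threshold = best$q, accuracy = best$acc / n)
}

#' Calibrate a plane's threshold on labelled samples
#'
#' Projects the calibration samples and learns the optimal threshold for
#' deciding between the plane's two classes (first class of the pair =
#' positive side).  Samples of other classes are ignored.
#'
#' @param plane a [SeparatingPlane-class].
#' @param data an [ExpressionDataset-class] restricted to the plane's
#'   features, or a samples-x-k matrix.
#' @param codes class code per sample (taken from \code{data} when it is an
#'   \code{ExpressionDataset}).
#' @return A [CalibratedPlane-class].
#' @export
calibratePlane <- function(plane, data, codes = NULL) {
  if (is(data, "ExpressionDataset")) {
    if (is.null(codes)) codes <- classCodes(data)
    data <- expressionMatrix(data)
  }
  keep <- codes %in% plane@pair
  if (!any(keep)) stop("no calibration samples of the plane's classes")
  proj <- planeProjection(data[keep, , drop = FALSE], plane)
  opt <- optimalThreshold(proj, codes[keep] == plane@pair[1])
  new("CalibratedPlane", plane = plane, threshold = opt$threshold,
      calibrationAccuracy = opt$accuracy)
}

#' Calibrate every plane of a pairwise battery
#'
#' @param planes named list of [SeparatingPlane-class] (from
#'   [fitAllPairs()]).
#' @param data calibration [ExpressionDataset-class] (training samples by
#'   default; pass the full dataset to calibrate on all samples).
#' @return Named list of [CalibratedPlane-class].
#' @export
calibrateAllPlanes <- function(planes, data) {
  codes <- classCodes(data)
  m <- expressionMatrix(data)
  lapply(planes, calibratePlane, data = m, codes = codes)
}

setMethod("show", "CalibratedPlane", function(object) {
  cat(sprintf("CalibratedPlane P_%s%s: threshold %.4g, calibration accuracy %.3f\n",
              object@plane@pair[1], object@plane@pair[2], object@threshold,
              object@calibrationAccuracy))
})

#' Classify samples by pairwise voting
#'
#' Each calibrated plane casts one vote per sample: for the pair
#' \eqn{(i, j)}, class \eqn{i} if \eqn{w \cdot x > Q^*}, else class
#' \eqn{j}; the most-voted class wins.  Vote ties are broken by the largest
#' sum of \eqn{|w \cdot x - Q^*|} over the tied classes' planes, then by the
#' smallest class code.
#'
#' @param samples samples-x-k matrix or [ExpressionDataset-class].
#' @param planes named list of [CalibratedPlane-class] covering all pairs
#'   of the class set.
#' @param nClasses number of classes; inferred from the planes when absent.
#' @return Integer vector of predicted class codes.
#' @export
classifyVote <- function(samples, planes, nClasses = NULL) {
  if (is(samples, "ExpressionDataset")) samples <- expressionMatrix(samples)
  pairs <- t(vapply(planes, function(p) p@plane@pair, integer(2)))
  codes <- sort(unique(as.vector(pairs)))
  if (is.null(nClasses)) nClasses <- max(codes)
  need <- utils::combn(codes, 2)
  have <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  if (!all(paste(need[1, ], need[2, ]) %in% have))
    stop("planes do not cover every class pair")
  n <- nrow(samples)
  votes <- matrix(0L, n, nClasses)
  margin <- matrix(0, n, nClasses)   # summed |w.x - Q*| per class
  for (p in planes) {
    proj <- planeProjection(samples, p)
    up <- proj > p@threshold
    i <- p@plane@pair[1]; j <- p@plane@pair[2]
    votes[, i] <- votes[, i] + up
    votes[, j] <- votes[, j] + !up
    d <- abs(proj - p@threshold)
    margin[, i] <- margin[, i] + d
    margin[, j] <- margin[, j] + d
  }
  vapply(seq_len(n), function(s) {
    tied <- which(votes[s, ] == max(votes[s, ]))
    if (length(tied) > 1)
      tied <- tied[margin[s, tied] == max(margin[s, tied])]
    tied[1]
  }, integer(1))
}

#' Build a decision-list node
#'
#' @param set candidate class codes at the node.
#' @param plane name of the plane (key into the calibrated-plane list).
#' @param threshold decision threshold at this node.
#' @param left classes retained when the projection exceeds the threshold.
#' @param right classes retained otherwise.
#' @return A decision node (list).
#' @export
decisionNode <- function(set, plane, threshold, left, right) {
  if (!length(left) || !length(right)) stop("both branches must be nonempty")
  if (!all(c(left, right) %in% set) || !setequal(union(left, right), set))
    stop("left/right must cover the candidate set")
  list(set = sort(as.integer(set)), plane = plane,
       threshold = threshold, left = sort(as.integer(left)),
       right = sort(as.integer(right)))
}

#' Classify samples by a decision list of thresholded planes
#'
#' Starting from the node whose candidate set is the full class set, each
#' step projects the sample on the node's plane and descends to the
#' \code{left} class set if the projection exceeds the node's threshold,
#' else to the \code{right} set, until a singleton remains.  Branch sets may
#' overlap (an ambiguous class can be resolvable on either branch).
#'
#' @param samples samples-x-k matrix or [ExpressionDataset-class].
#' @param nodes list of nodes from [decisionNode()].
#' @param planes named list of [SeparatingPlane-class] or
#'   [CalibratedPlane-class]; node thresholds override calibrated ones.
#' @return Integer vector of predicted class codes.
#' @export
classifyDecisionList <- function(samples, nodes, planes) {
  if (is(samples, "ExpressionDataset")) samples <- expressionMatrix(samples)
  keyOf <- function(set) paste(sort(set), collapse = ",")
  byset <- stats::setNames(nodes, vapply(nodes, function(n) keyOf(n$set),
                                         character(1)))
  root <- nodes[[1]]$set
  vapply(seq_len(nrow(samples)), function(s) {
    x <- samples[s, , drop = FALSE]
    cur <- root
    for (step in seq_len(length(nodes) + 1L)) {
      if (length(cur) == 1L) return(as.integer(cur))
      nd <- byset[[keyOf(cur)]]
      if (is.null(nd))
        stop("no decision node for candidate set {",
             paste(cur, collapse = ","), "}")
      pl <- planes[[nd$plane]]
      proj <- planeProjection(x, pl)
      cur <- if (proj > nd$threshold) nd$left else nd$right
    }
    stop("decision list did not reach a singleton class")
  }, integer(1))
}

#' Greedily build a decision list from calibrated planes
#'
#' At each candidate set, every plane (at its calibrated threshold) is
#' scored by how accurately the side each class's samples fall on (by
#' majority) explains the samples; the best plane with two nonempty
#' branches becomes the node, and the construction recurses on each branch.
#' The published threshold tables for this classifier give no construction
#' algorithm, so the list is either user-supplied or built by this greedy
#' heuristic.
#'
#' @param planes named list of [CalibratedPlane-class].
#' @param data labelled [ExpressionDataset-class] used to drive the greedy
#'   choice.
#' @return List of decision nodes suitable for [classifyDecisionList()].
#' @export
greedyDecisionList <- function(planes, data) {
  codes <- classCodes(data)
  m <- expressionMatrix(data)
  build <- function(set) {
    if (length(set) <= 1) return(list())
    rows <- which(codes %in% set)
    best <- NULL
    for (nm in names(planes)) {
      p <- planes[[nm]]
      proj <- planeProjection(m[rows, , drop = FALSE], p)
      up <- proj > p@threshold
      side <- vapply(set, function(cl)
        mean(up[codes[rows] == cl]) > 0.5, logical(1))
      left <- set[side]; right <- set[!side]
      if (!length(left) || !length(right)) next
      correct <- sum(up & codes[rows] %in% left) +
        sum(!up & codes[rows] %in% right)
      if (is.null(best) || correct > best$correct) {
        best <- list(correct = correct, nm = nm, p = p,
                     left = left, right = right)
      }
    }
    if (is.null(best))
      stop("no plane splits candidate set {",
           paste(set, collapse = ","), "}")
    node <- decisionNode(set, best$nm, best$p@threshold,
                         best$left, best$right)
    c(list(node), build(best$left), build(best$right))
  }
  build(sort(unique(codes)))
}
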