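#' Build the pairwise L1-slack separability LP
#'
#' For point sets \eqn{D_i} (positive class, \eqn{n_i \times k}) and
#' \eqn{D_j} (negative class, \eqn{n_j \times k}) the program seeks a
#' weight vector \eqn{w} and bias \eqn{b} with
#' \eqn{w \cdot d_u - b \ge 1} on the positive side and
#' \eqn{w \cdot d_v - b \le -1} on the negative side, relaxed by
#' nonnegative slacks \eqn{y_u, z_v} and the class-size-normalized
#' objective \eqn{\min (1/n_i)\sum_u y_u + (1/n_j)\sum_v z_v}.  The optimal
#' value is 0 exactly when the two sets are linearly separable.
#'
#' @param Di,Dj numeric matrices with equal column count \code{k}.
#' @return An [LPProblem-class].
#' @export
buildPairLP <- function(Di, Dj) {
  Di <- as.matrix(Di); Dj <- as.matrix(Dj)
  if (ncol(Di) != ncol(Dj)) stop("dimension mismatch between the two sets")
  k <- ncol(Di); ni <- nrow(Di); nj <- nrow(Dj)
  if (k < 1 || ni < 1 || nj < 1) stop("need k >= 1 and nonempty classes")
  # variables (w, b, y, z); rows: w.d_u - b + y_u >= 1 ; -w.d_v + b + z_v >= 1
  A <- rbind(
    cbind(Di, -1, diag(ni), matrix(0, ni, nj)),
    cbind(-Dj, 1, matrix(0, nj, ni), diag(nj)))
  new("LPProblem", constraints = unname(A), rhs = rep(1, ni + nj),
      objective = c(rep(0, k + 1), rep(1 / ni, ni), rep(1 / nj, nj)),
      weightDim = as.integer(k), nPos = as.integer(ni),
      nNeg = as.integer(nj))
}

#' Solve the pairwise LP for a separating plane
#'
#' Free variables \eqn{(w, b)} are split into nonnegative parts before the
#' internal simplex solver is called; the recovered plane and objective are
#' unaffected by the splitting.  The plane is flagged separable when the
#' optimal objective is within \code{tol} of zero.
#'
#' @param problem an [LPProblem-class].
#' @param pair integer class codes (positive, negative).
#' @param tol separability tolerance on the objective (default 1e-6).
#' @param pairLabels optional class labels.
#' @return A [SeparatingPlane-class].
#' @export
solvePlane <- function(problem, pair = c(1L, 2L), tol = 1e-6,
                       pairLabels = as.character(pair)) {
  k <- problem@weightDim; ni <- problem@nPos; nj <- problem@nNeg
  A <- problem@constraints
  free <- A[, seq_len(k + 1), drop = FALSE]
  slack <- A[, k + 1 + seq_len(ni + nj), drop = FALSE]
  Asplit <- cbind(free, -free, slack)
  objSplit <- c(rep(0, 2 * (k + 1)), problem@objective[k + 1 + seq_len(ni + nj)])
  sol <- .lpSimplex(objSplit, Asplit, problem@rhs)
  if (sol$status != 0L)
    stop("internal LP solver failure (status ", sol$status,
         "); the slack objective is bounded below by 0, so this indicates ",
         "a malformed problem")
  xf <- sol$x[seq_len(k + 1)] - sol$x[k + 1 + seq_len(k + 1)]
  obj <- max(0, sol$value)
  new("SeparatingPlane", pair = as.integer(pair),
      pairLabels = as.character(pairLabels),
      weights = xf[seq_len(k)], bias = xf[k + 1],
      objectiveValue = obj, separable = obj <= tol,
      solverStatus = "optimal")
}

setMethod("show", "SeparatingPlane", function(object) {
  cat(sprintf("SeparatingPlane P_%s%s: objective %.3g (%s), k = %d\n",
              object@pair[1], object@pair[2], object@objectiveValue,
              if (object@separable) "separable" else "not separable",
              length(object@weights)))
})

#' Fit separating planes for all class pairs
#'
#' One plane per unordered class pair, in the order (1,2), (1,3), ...,
#' (c-1,c).  The first class of each pair takes the positive side.
#'
#' @param train an [ExpressionDataset-class], already restricted to the
#'   selected features (and typically normalized).
#' @param tol separability tolerance.
#' @return Named list of [SeparatingPlane-class] objects
#'   (\code{"1|2"}, \code{"1|3"}, ...).
#' @export
fitAllPairs <- function(train, tol = 1e-6) {
  codes <- classCodes(train)
  cs <- classSet(train)
  present <- sort(unique(codes))
  if (length(present) < 2) stop("plane fitting needs >= 2 classes")
  m <- expressionMatrix(train)
  planes <- list()
  for (ai in seq_along(present)) for (bi in seq_along(present)) {
    if (bi <= ai) next
    i <- present[ai]; j <- present[bi]
    Di <- m[codes == i, , drop = FALSE]
    Dj <- m[codes == j, , drop = FALSE]
    if (!nrow(Di) || !nrow(Dj)) stop("empty class in pair (", i, ",", j, ")")
    pl <- solvePlane(buildPairLP(Di, Dj), pair = c(i, j), tol = tol,
                     pairLabels = cs[c(i, j)])
    planes[[paste0(i, "|", j)]] <- pl
  }
  planes
}

#' Merge classes into a super-class
#'
#' Relabels every sample whose class is in \code{mergeSet} with
#' \code{newLabel}; expression values are untouched.  The class set is
#' recomputed in first-appearance order of the new labels.
#'
#' @param x an [ExpressionDataset-class].
#' @param mergeSet class labels (or integer codes) to merge.
#' @param newLabel label of the merged class; defaults to the merged labels
#'   joined with \code{"&"}.
#' @return An [ExpressionDataset-class].
#' @export
mergeClasses <- function(x, mergeSet, newLabel = NULL) {
  cs <- classSet(x)
  if (is.numeric(mergeSet)) {
    if (any(mergeSet < 1 | mergeSet > length(cs)))
      stop("unknown class code in mergeSet")
    mergeSet <- cs[mergeSet]
  }
  if (!all(mergeSet %in% cs)) stop("unknown class in mergeSet")
  if (is.null(newLabel)) newLabel <- paste(mergeSet, collapse = "&")
  lab <- classLabels(x)
  lab[lab %in% mergeSet] <- newLabel
  ExpressionDataset(expressionMatrix(x), labels = lab,
                    sampleIds = sampleIds(x), probeIds = probeIds(x))
}
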