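#' Score features for class separability
#'
#' Computes the per-feature selection measure \eqn{d_i}.  The default
#' \code{"margin"} mode measures, on the normalized values, the largest
#' one-dimensional inter-class gap
#' \deqn{d_i = \max_{(a,b)} \max\!\big(0,\; \min_{s \in a} z_{si} -
#'   \max_{s \in b} z_{si}\big)}
#' over ordered class pairs \eqn{(a, b)}: \eqn{d_i > 0} exactly when a
#' threshold on feature \eqn{i} alone perfectly splits some class pair.
#' The \code{"literal"} mode applies the floor-at-zero column minimum
#' \eqn{d_i = \max(0, \min_j x_{ji})} to the class-centered concatenated
#' matrix; because per-class mean removal forces every non-constant centered
#' column to have a nonpositive minimum, this mode returns 0 for all such
#' features and is retained only for fidelity to the formula as printed.
#'
#' @param centered a [ClassCenteredMatrix-class] (used by \code{"literal"}).
#' @param normalized samples-x-features matrix of normalized values (used by
#'   \code{"margin"}).
#' @param codes integer class code per row of \code{normalized}.
#' @param mode \code{"margin"} (default) or \code{"literal"}.
#' @return A [FeatureScores-class].
#' @export
scoreFeatures <- function(centered, normalized, codes,
                          mode = c("margin", "literal")) {
  mode <- match.arg(mode)
  if (mode == "literal") {
    x <- centered@centered
    scores <- pmax(0, apply(x, 2, min))
  } else {
    normalized <- as.matrix(normalized)
    codes <- as.integer(codes)
    cls <- sort(unique(codes))
    if (length(cls) < 2) stop("margin scoring needs >= 2 classes")
    p <- ncol(normalized)
    mins <- matrix(vapply(cls, function(c)
      apply(normalized[codes == c, , drop = FALSE], 2, min),
      numeric(p)), nrow = p)
    maxs <- matrix(vapply(cls, function(c)
      apply(normalized[codes == c, , drop = FALSE], 2, max),
      numeric(p)), nrow = p)
    scores <- rep(0, ncol(normalized))
    for (a in seq_along(cls)) for (b in seq_along(cls)) if (a != b)
      scores <- pmax(scores, mins[, a] - maxs[, b])
    scores <- pmax(0, scores)
  }
  ranking <- order(-scores, seq_along(scores))
  new("FeatureScores", scores = unname(scores), mode = mode,
      ranking = as.integer(ranking))
}

#' Select the top-k features
#'
#' Takes the first \code{k} features of the ranking (descending score, ties
#' broken by ascending feature index).  Feature indices are 1-based file
#' order, matching how probe columns are numbered in the source CSV.
#'
#' @param scores a [FeatureScores-class].
#' @param k number of features to keep (default 25).
#' @param probeIds optional probe identifiers to attach.
#' @return A [SelectedFeatures-class].
#' @export
selectTopK <- function(scores, k = 25, probeIds = NULL) {
  p <- length(scores@scores)
  if (k < 1 || k > p) stop("k must be in 1..", p)
  idx <- scores@ranking[seq_len(k)]
  pid <- if (is.null(probeIds)) sprintf("feature_%d", idx) else probeIds[idx]
  new("SelectedFeatures", k = as.integer(k), indices = idx,
      probeIds = as.character(pid))
}

#' Restrict a dataset to selected features
#'
#' Output columns follow selection order, not source order; sample metadata
#' and labels are unchanged.
#'
#' @param x an [ExpressionDataset-class].
#' @param selected a [SelectedFeatures-class] or an integer index vector.
#' @return An [ExpressionDataset-class] with \code{k} features.
#' @export
restrictFeatures <- function(x, selected) {
  idx <- if (is(selected, "SelectedFeatures")) selected@indices
         else as.integer(selected)
  if (any(idx < 1 | idx > nrow(x))) stop("feature index out of range")
  x[idx, ]
}

#' Feature ranking report
#'
#' A data.frame mirroring the published feature table layout: rank,
#' 1-based feature number, probe-set ID and score.
#'
#' @param scores a [FeatureScores-class].
#' @param probeIds probe identifiers.
#' @param k how many rows to report.
#' @return data.frame with columns \code{rank}, \code{feature_no},
#'   \code{probe_set_id}, \code{score}.
#' @export
featureReport <- function(scores, probeIds, k = 25) {
  idx <- scores@ranking[seq_len(min(k, length(scores@scores)))]
  data.frame(rank = seq_along(idx), feature_no = idx,
             probe_set_id = probeIds[idx], score = scores@scores[idx],
             stringsAsFactors = FALSE)
}
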