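#' Confusion matrix
#'
#' Rows are actual groups, columns predicted groups, in the supplied group
#' order.
#'
#' @param actual,predicted label vectors of equal length; every value must
#'   be a member of \code{groups}.
#' @param groups ordered group labels.
#' @return Integer matrix with group dimnames.
#' @export
confusionCounts <- function(actual, predicted, groups) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length")
  bad <- setdiff(c(actual, predicted), groups)
  if (length(bad)) stop("label outside groups: ", paste(bad, collapse = ", "))
  tab <- table(factor(actual, levels = groups),
               factor(predicted, levels = groups))
  m <- matrix(as.integer(tab), length(groups), length(groups),
              dimnames = list(actual = groups, predicted = groups))
  m
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' Standard definitions: with rows = actual and columns = predicted,
#' per-group recall is \code{diag/rowSums} and precision \code{diag/colSums};
#' F1 is their harmonic mean and accuracy is \code{100 * trace / total}.
#' \code{roundingMode = "paper"} rounds each per-group metric to 2 decimal
#' places before macro-averaging (the convention of the published metric
#' table); \code{"exact"} averages unrounded values.
#' \code{paperOrientation = TRUE} additionally swaps the precision and
#' recall column names in the report, reproducing the published table's
#' column placement (its "Precision" column holds row-normalized diagonals,
#' i.e. standard recall); F1 is unaffected since it is symmetric in the two
#' fractions.
#'
#' A predicted class that never occurs (zero column) gets precision 1
#' (vacuously no false positives); a group with no actual samples is an
#' error.
#'
#' @param cm confusion matrix from [confusionCounts()].
#' @param roundingMode \code{"exact"} or \code{"paper"}.
#' @param paperOrientation swap the precision/recall column names.
#' @return list with \code{accuracy} (percent), \code{perClass} data.frame
#'   and \code{macro} named vector.
#' @export
classificationMetrics <- function(cm, roundingMode = c("exact", "paper"),
                                  paperOrientation = FALSE) {
  roundingMode <- match.arg(roundingMode)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix")
  rs <- rowSums(cm); cs <- colSums(cm); d <- diag(cm)
  if (any(rs == 0)) stop("group with no actual samples: ",
                         paste(rownames(cm)[rs == 0], collapse = ", "))
  recall <- d / rs
  precision <- ifelse(cs == 0, 1, d / cs)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  if (roundingMode == "paper") {
    precision <- round(precision, 2); recall <- round(recall, 2)
    f1 <- round(f1, 2)
  }
  perClass <- data.frame(class = rownames(cm), precision = precision,
                         recall = recall, f1 = f1, row.names = NULL,
                         stringsAsFactors = FALSE)
  macro <- c(precision = mean(precision), recall = mean(recall),
             f1 = mean(f1))
  if (paperOrientation) {
    colnames(perClass)[2:3] <- c("recall", "precision")
    perClass <- perClass[, c("class", "precision", "recall", "f1")]
    names(macro)[1:2] <- c("recall", "precision")
    macro <- macro[c("precision", "recall", "f1")]
  }
  list(accuracy = 100 * sum(d) / total, perClass = perClass, macro = macro,
       roundingMode = roundingMode)
}

#' Pairwise binary precision table
#'
#' For each unordered group pair \eqn{(i, j)}, evaluates the calibrated
#' plane \eqn{P_{ij}} on the samples of groups \eqn{i} and \eqn{j} only and
#' counts correct binary decisions out of \eqn{n_i + n_j}.
#'
#' @param data labelled [ExpressionDataset-class] restricted to the planes'
#'   features.
#' @param planes named list of [CalibratedPlane-class].
#' @return data.frame with columns \code{i}, \code{j}, \code{labelI},
#'   \code{labelJ}, \code{correct}, \code{total}; one row per plane, in
#'   plane order.
#' @export
pairwisePrecision <- function(data, planes) {
  codes <- classCodes(data)
  cs <- classSet(data)
  m <- expressionMatrix(data)
  rows <- lapply(planes, function(p) {
    i <- p@plane@pair[1]; j <- p@plane@pair[2]
    keep <- codes %in% c(i, j)
    if (!any(keep))
      return(data.frame(i = i, j = j, labelI = cs[i], labelJ = cs[j],
                        correct = 0L, total = 0L))
    proj <- planeProjection(m[keep, , drop = FALSE], p)
    up <- proj > p@threshold
    correct <- sum(up & codes[keep] == i) + sum(!up & codes[keep] == j)
    data.frame(i = i, j = j, labelI = cs[i], labelJ = cs[j],
               correct = as.integer(correct), total = as.integer(sum(keep)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Format a pairwise precision table as an upper-triangular display
#'
#' @param tab data.frame from [pairwisePrecision()].
#' @return Character matrix with \code{"correct/total"} entries above the
#'   diagonal.
#' @export
formatPairwise <- function(tab) {
  cls <- sort(unique(c(tab$i, tab$j)))
  out <- matrix("", length(cls), length(cls),
                dimnames = list(cls, cls))
  for (r in seq_len(nrow(tab)))
    out[match(tab$i[r], cls), match(tab$j[r], cls)] <-
      sprintf("%d/%d", tab$correct[r], tab$total[r])
  out
}
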